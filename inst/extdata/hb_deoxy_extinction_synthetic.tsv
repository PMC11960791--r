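# Molar extinction coefficient of deoxyhemoglobin (Hb), cm^-1 / (mol/L),
# tabulated against wavelength (nm), decadic convention.
# SYNTHETIC REFERENCE TABLE: values transcribed/smoothed to reproduce the
# shape and magnitudes of the standard compiled whole-blood hemoglobin
# extinction tables (Gratzer/Kollias compilation as distributed by the Oregon
# Medical Laser Center); knots are approximate, not the original data file.
# Soret maximum near 434 nm; single Q band near 556 nm; secondary bump near
# 760 nm; 664 nm included as an explicit knot.
# Conversion to whole-blood mua uses ln(10) * eps * C_hb / MW with
# C_hb = 150 g/L and MW = 64500 g/mol (see chromophore_library()).
# wavelength_nm	eps_cm1_per_M
250	80000
280	70000
300	40000
320	36000
340	38000
360	45000
380	70000
390	110000
400	223296
410	303956
420	407560
425	470000
430	528600
434	553232
440	413280
445	250000
450	105000
460	60000
470	42000
480	30000
490	24000
500	20862
510	25773
520	31589
530	39036
540	46592
546	50000
550	53236
556	53412
560	53236
566	50000
570	45072
576	41000
580	37020
586	32000
590	26600
596	20000
600	14677
610	9443
620	6509
630	5148
640	4345
650	3750
660	3227
664	3130
670	2940
680	2457
690	2101
700	1794
710	1621
720	1465
730	1380
740	1365
750	1405
756	1530
760	1548
770	1390
780	1180
790	940
800	762
820	693
840	693
860	710
880	720
900	750
920	790
940	800
960	780
980	740
1000	700
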