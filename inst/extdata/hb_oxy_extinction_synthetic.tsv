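# Molar extinction coefficient of oxyhemoglobin (HbO2), cm^-1 / (mol/L),
# tabulated against wavelength (nm), decadic convention.
# SYNTHETIC REFERENCE TABLE: values transcribed/smoothed to reproduce the
# shape and magnitudes of the standard compiled whole-blood hemoglobin
# extinction tables (Gratzer/Kollias compilation as distributed by the Oregon
# Medical Laser Center); knots are approximate, not the original data file.
# Soret maximum near 414 nm; Q bands near 542 and 576 nm; red-region minimum
# near 690 nm; 664 nm included as an explicit knot.
# Conversion to whole-blood mua uses ln(10) * eps * C_hb / MW with
# C_hb = 150 g/L and MW = 64500 g/mol (see chromophore_library()).
# wavelength_nm	eps_cm1_per_M
250	105000
280	75000
300	41000
320	32000
340	32000
360	35000
380	50000
390	92000
400	266232
405	350000
410	466840
414	523160
420	480360
425	351000
430	246072
435	170000
440	102580
445	80000
450	62816
460	44480
470	34639
480	26629
490	23684
500	20932
510	20035
520	24202
530	39956
536	48000
540	53236
542	54164
546	52000
550	49896
554	44000
560	32620
568	35000
572	41000
576	45072
580	38000
584	26000
588	14000
592	8000
596	5000
600	3200
605	2100
610	1506
620	942
630	610
640	442
650	368
660	320
664	310
670	294
680	278
690	276
700	290
710	314
720	334
740	446
750	518
760	586
780	710
800	816
820	916
840	1022
860	1092
880	1154
900	1198
920	1240
940	1248
960	1220
980	1162
1000	1086
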