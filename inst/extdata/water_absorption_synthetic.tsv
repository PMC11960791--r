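# Absorption coefficient of pure water, cm^-1, against wavelength (nm).
# SYNTHETIC REFERENCE TABLE: values transcribed/smoothed from the standard
# compiled pure-water absorption measurements (Hale & Querry / Pope & Fry
# compilations); knots are approximate, not the original data files.
# Water absorption is negligible below ~600 nm and rises steeply toward the
# near infrared (970 nm band).
# wavelength_nm	mua_cm1
250	0.00059
300	0.00015
350	0.00007
400	0.000058
450	0.000092
500	0.00025
550	0.000565
600	0.0022
620	0.0028
650	0.0034
664	0.0042
680	0.005
700	0.006
720	0.0105
740	0.0225
750	0.026
760	0.0256
780	0.0224
800	0.0206
820	0.0237
840	0.0324
860	0.0457
880	0.0562
900	0.0679
920	0.1123
940	0.2644
950	0.388
970	0.45
980	0.43
1000	0.36
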