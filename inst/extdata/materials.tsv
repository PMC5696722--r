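# kvseg material database: tissue-substitute phantom plastics (manufacturer
# reference values) and ICRU Report 44 tissues used for the rodent phantom.
# columns (tab-separated): name, groups (comma list), rho_g_cm3, ref_rho_e,
#   ref_z_eff, composition (element:mass-percent pairs, semicolon-separated)
name	groups	rho	rho_e	z_eff	composition
AP6	calibration	0.947	0.928	6.210	H:9.06;C:72.30;N:2.25;O:16.27;F:0.13
Solid Water	calibration,validation	1.022	0.992	7.735	H:8.00;C:67.30;N:2.39;O:19.87;Cl:0.14;Ca:2.31
IB3	calibration	1.134	1.086	10.418	H:6.67;C:55.64;N:1.96;O:23.52;P:3.23;Cl:0.11;Ca:8.86
SR2	calibration	1.051	1.047	6.090	H:10.83;C:72.54;N:1.69;O:14.86;Cl:0.08
CB2-30%	calibration	1.331	1.276	10.898	H:6.68;C:53.48;N:2.12;O:25.61;Cl:0.11;Ca:12.01
BR12	calibration,validation	0.980	0.956	6.931	H:8.59;C:70.11;N:2.33;O:17.90;Cl:0.13;Ca:0.95
Air	calibration,validation,mouse	0.001	0.001	7.714	N:75.47;O:23.20;Ar:1.28
Water	calibration,validation	1.000	1.000	7.477	H:11.20;O:88.80
B200	calibration	1.152	1.103	10.423	H:6.65;C:55.52;N:1.98;O:23.64;P:3.24;Cl:0.11;Ca:8.87
LV1	calibration	1.096	1.064	7.736	H:8.06;C:67.01;N:2.47;O:20.01;Cl:0.14;Ca:2.31
SB3	calibration	1.822	1.695	13.638	H:3.41;C:31.41;N:1.84;O:36.50;Cl:0.04;Ca:26.81
CB2-50%	calibration	1.559	1.469	12.538	H:4.77;C:41.63;N:1.52;O:32.00;Cl:0.08;Ca:20.02
Teflon	validation	2.153	1.860	8.461	C:24.00;F:76.00
Lucite	validation	1.180	1.146	6.529	H:8.05;C:59.98;O:31.96
PMMA	validation	1.190	1.156	6.529	H:8.05;C:59.98;O:31.96
Paraffin	validation	0.930	0.959	5.483	H:14.90;C:85.10
Muscle	validation	1.062	1.041	7.588	H:9.10;C:69.70;N:2.10;O:16.80;Cl:0.10;Ca:2.20
Adipose	validation	0.967	0.956	6.439	H:10.00;C:71.30;N:1.80;O:16.40;Cl:0.20;Ca:0.30
Bone	validation	1.600	1.507	11.895	H:4.83;C:37.03;N:0.97;O:35.66;Mg:6.19;Cl:0.05;Ca:15.24
ICRU Adipose	mouse	0.93	0.951	6.421	H:11.60;C:68.10;N:0.20;O:19.80;Na:0.10;S:0.10;Cl:0.10
Brain	mouse	1.04	1.035	7.578	H:10.70;C:14.50;N:2.20;O:71.20;Na:0.20;P:0.40;S:0.20;Cl:0.30;K:0.30
Spongiosa	mouse	1.18	1.151	10.230	H:8.50;C:40.40;N:2.80;O:36.70;Na:0.10;Mg:0.20;P:3.40;S:0.20;Cl:0.20;K:0.10;Ca:7.40;Fe:0.10
Cranium	mouse	1.61	1.517	12.709	H:5.00;C:21.20;N:4.00;O:43.50;Na:0.10;Mg:0.20;P:8.10;S:0.30;Ca:17.60
Cortical Bone	mouse	1.92	1.780	13.629	H:3.40;C:15.50;N:4.20;O:43.50;Na:0.10;Mg:0.20;P:10.30;S:0.30;Ca:22.50
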