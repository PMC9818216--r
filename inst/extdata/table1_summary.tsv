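parameter	ctrl_mean	ctrl_sd	ctrl_n	lc_mean	lc_sd	lc_n	hcc_mean	hcc_sd	hcc_n
Age (Year)	56.7	9.8	17	65.2	11.4	18	70.2	5.0	10
BMI	23.1	1.51	17	26.2	3.6	18	25.0	4.1	10
AST (U/L)	30.9	3.5	17	35.6	10.8	18	43.3	17.1	10
ALT (U/L)	28.5	4.7	17	30.0	17.9	18	48.1	30.0	10
Bilirubin (mg/dL)	NA	NA	NA	1.1	0.5	18	1.2	0.7	10
Albumin (g/dL)	NA	NA	NA	4.4	0.4	18	3.6	0.5	10
T-Cholesterol (mg/dL)	NA	NA	NA	166.6	26.1	18	150.0	40.3	10
Triglyceride (mg/dL)	NA	NA	NA	108.6	54.8	18	99.4	59.1	10
HbA1c (%)	NA	NA	NA	6.1	1.2	18	6.1	0.9	10
Platelet (1000/uL)	NA	NA	NA	120.2	45.8	18	100.7	43.6	10
Child-Pugh score	NA	NA	NA	5.1	0.2	18	6.0	1.6	10
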