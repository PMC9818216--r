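center	center_layer	ALL	CTRL_LC	CTRL_HCC	LC_HCC	ctrl_mean	lc_mean	hcc_mean	published_label	published_severity
Ruminococcus gnavus group	bacteria	TRUE	FALSE	TRUE	FALSE	NA	NA	NA	HCC specific	-
Succinatimonas	bacteria	TRUE	TRUE	FALSE	FALSE	NA	NA	NA	LC specific	-
Enterobacter	bacteria	FALSE	TRUE	FALSE	FALSE	NA	NA	NA	LC specific	-
Oxalobacter	bacteria	FALSE	FALSE	TRUE	FALSE	NA	NA	NA	HCC specific	-
Ruminococcaceae UCG 002	bacteria	FALSE	FALSE	FALSE	TRUE	NA	NA	NA	-	Yes
Ruminococcaceae UCG 005	bacteria	FALSE	FALSE	FALSE	TRUE	NA	NA	NA	-	Yes
Negativibacillus	bacteria	FALSE	FALSE	FALSE	TRUE	NA	NA	NA	-	Yes
Tyzzerella 3	bacteria	FALSE	FALSE	FALSE	TRUE	NA	NA	NA	-	Yes
Stenotrophomonas virus DLP5	virus	TRUE	TRUE	TRUE	FALSE	NA	NA	NA	Common	-
Uncultured Caudovirales phage	virus	TRUE	TRUE	TRUE	TRUE	NA	NA	NA	Common	Yes
Escherichia virus ECBP5	virus	FALSE	TRUE	FALSE	FALSE	NA	NA	NA	LC specific	-
Uncultured Mediterranean phage uvMED	virus	FALSE	TRUE	FALSE	FALSE	NA	NA	NA	LC specific	-
Actinomyces virus Av1	virus	FALSE	FALSE	FALSE	TRUE	NA	NA	NA	-	Yes
Azobacteroides phage ProJPt-Bp1	virus	FALSE	FALSE	FALSE	TRUE	NA	NA	NA	-	Yes
Bacteroides phage B124-14	virus	FALSE	FALSE	FALSE	TRUE	NA	NA	NA	-	Yes
Bacteroides phage B40-8	virus	FALSE	FALSE	FALSE	TRUE	NA	NA	NA	-	Yes
Clostridium phage phiCTP1	virus	FALSE	FALSE	FALSE	TRUE	NA	NA	NA	-	Yes
Flavobacterium phage Fpv3	virus	FALSE	FALSE	FALSE	TRUE	NA	NA	NA	-	Yes
Pectobacterium phage DU_PP_III	virus	FALSE	FALSE	FALSE	TRUE	NA	NA	NA	-	Yes
Streptococcus phage Dp-1	virus	FALSE	FALSE	FALSE	TRUE	NA	NA	NA	-	Yes
Threonine	metabolite	TRUE	FALSE	TRUE	TRUE	NA	NA	NA	HCC specific	Yes
Pyruvic acid	metabolite	TRUE	TRUE	TRUE	FALSE	NA	NA	NA	Common	-
Leucine	metabolite	TRUE	FALSE	TRUE	FALSE	NA	NA	NA	HCC specific	-
Acetic acid	metabolite	TRUE	FALSE	FALSE	FALSE	39.1	150.8	200.5	Common *	-
Methionine	metabolite	FALSE	FALSE	TRUE	FALSE	NA	NA	NA	HCC specific	-
Formic acid	metabolite	FALSE	FALSE	FALSE	TRUE	NA	NA	NA	-	Yes
3-hydroxybutyric acid	metabolite	FALSE	FALSE	FALSE	TRUE	NA	NA	NA	-	Yes
Succinic acid	metabolite	FALSE	FALSE	FALSE	TRUE	NA	NA	NA	-	Yes
Eotaxin	cytokine	TRUE	TRUE	TRUE	FALSE	NA	NA	NA	Common	-
IL-1b	cytokine	TRUE	TRUE	FALSE	FALSE	NA	NA	NA	LC specific	-
MCP-1	cytokine	TRUE	TRUE	FALSE	TRUE	NA	NA	NA	LC specific	Yes
PDGF-AB/BB	cytokine	TRUE	FALSE	FALSE	FALSE	17.9	75.9	51.6	Common *	-
IL-10	cytokine	FALSE	TRUE	FALSE	TRUE	NA	NA	NA	LC specific	Yes
FGF-2	cytokine	FALSE	TRUE	FALSE	FALSE	NA	NA	NA	LC specific	-
IL-17A	cytokine	FALSE	FALSE	TRUE	FALSE	NA	NA	NA	HCC specific	-
MIP-1b	cytokine	FALSE	FALSE	TRUE	FALSE	NA	NA	NA	HCC specific	-
IL-8	cytokine	FALSE	FALSE	TRUE	FALSE	NA	NA	NA	HCC specific	-
GM-CSF	cytokine	FALSE	FALSE	FALSE	TRUE	NA	NA	NA	-	Yes
RANTES	cytokine	FALSE	FALSE	FALSE	TRUE	NA	NA	NA	-	Yes
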