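snp_id	snp_location	region	gene	risk_allele	raf	cpg_id	cpg_location	cpg_gene	direction	effect_size
rs798766	chr4:1734239	4p16.3	TMEM129-TACC3-FGFR3	T	0.23	cg00006948	chr4:1768889		+	0.004
rs401681	chr5:1322087	5p15.33	TERT-CLPTM1L	C	0.53	cg27028750	chr5:1349422		+	0.059
rs401681	chr5:1322087	5p15.33	TERT-CLPTM1L	C	0.53	cg26209169	chr5:1316264		-	0.038
rs2294008	chr8:143761931	8q24.3	PSCA	T	0.49	cg06565975	chr8:143823917	SLURP1	-	0.041
rs2294008	chr8:143761931	8q24.3	PSCA	T	0.49	cg03405983	chr8:143858548	LYNX1	-	0.009
rs2294008	chr8:143761931	8q24.3	PSCA	T	0.49	cg24023258	chr8:143781297	LY6K	+	0.004
rs2294008	chr8:143761931	8q24.3	PSCA	T	0.49	cg17888033	chr8:143858414	LYNX1	-	0.020
rs2294008	chr8:143761931	8q24.3	PSCA	T	0.49	cg17252645	chr8:143867129	LY6D	-	0.042
rs8102137	chr19:30296853	19q12	CCNE1	C	0.32	cg16836589	chr19:30303674	CCNE1	-	0.011
rs8102137	chr19:30296853	19q12	CCNE1	C	0.32	cg27475126	chr19:30303651	CCNE1	-	0.049
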