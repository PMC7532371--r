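hsa00970	Aminoacyl-tRNA biosynthesis	GARS1	WARS	AARS1	HARS1	MARS1	YARS1	KARS1
hsa04962	Vasopressin-regulated water reabsorption	DCTN1	DCTN2	DYNC1H1
hsa00600	Sphingolipid metabolism	SGPL1	SPTLC2	SPTLC1
hsa05014	Amyotrophic lateral sclerosis	SOD1	NEFL	NEFH
hsa04145	Phagosome	TUBA8	RAB7A	DYNC1H1
hsa04978	Mineral absorption	ATP1A1	ATP7A
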