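# Partial Charcot-Marie-Tooth (CMT) seed gene list.
# A curated CMT disease gene set contains ~100 literature-reported genes;
# this file ships only the subset recoverable from published summaries
# (tRNA synthetases, cytochrome c oxidases, heat shock proteins, dynactins,
# kinesins, metabolic / mitochondrial / actin / myelin genes and the
# members of reported enriched pathways). It is a demo input, not the full set.
AARS1
GARS1
HARS1
KARS1
MARS1
WARS
YARS1
COA7
COX10
COX6A1
SCO2
DNAJB2
HSPB1
HSPB3
HSPB8
DCTN1
DCTN2
KIF1B
KIF5A
ABHD12
DGAT2
MORC2
HK1
NAGLU
PDK3
AIFM1
ATP1A1
DHTKD1
HADHB
MFN2
MPV17
POLG
REEP1
SLC25A46
SOD1
FGD4
FIG4
INF2
MICAL1
PFN2
MPZ
PMP22
PRX
GAMT
SGPL1
MTMR2
PRPS1
DNMT1
SPTLC2
SPTLC1
DYNC1H1
NEFL
NEFH
RAB7A
LMNA
TUBA8
DNM2
ATP7A
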