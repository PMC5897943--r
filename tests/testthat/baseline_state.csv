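species,concentration
EGFR,1.000000000000
IFNG,1.000000000000
PIK3CA,1.000000000000
STK11,1.000000000000
KEAP1,1.000000000000
CDKN2A,1.000000000000
TP53,0.704588416026
RAS,1.040000000000
RAF,1.073112582781
MEK,1.100193666579
ERK,1.122123348910
AP1,1.139739373049
AKT,1.040000000000
MTOR,1.051883394194
STAT3,0.735243662628
IFNGR1,1.040000000000
STAT1,1.073112582781
IRF1,1.100193666579
AMPK,0.706666666667
PDL1,0.599444618661
CCL2,0.756894156963
CCL3,0.822532738801
CCL4,0.808242387925
CCL5,0.856577804415
CCL7,0.896786012681
CCL11,0.429323623355
CCL20,0.701082009723
CX3CL1,0.971039286561
CXCL14,0.626181790944
TGFB1,1.055701855178
IDO1,0.657132452752
IL6,0.516654529194
VEGFA,1.144402023830
TDO2,0.729274009346
PGE2,0.782386036715
IL10,0.576865607778
LGALS9,0.786795777720
FASLG,0.808242387925
CD47,0.638973808751
CTLA4,0.896786012681
PDCD1LG2,0.575848408984
GM3,0.967001686525
GD2,0.971039286561
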