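gene	study	disease	pvalue	logfc
CAMK2G	GSE21942	MS	4.15E-04	-0.551
CAMK2G	GSE43591	MS	3.09E-06	-0.44
CAMK2G	GSE16561	IS	5.81E-01	0.043117
CAMK2G	GSE58294	IS	5.14E-07	0.352815
CLEC2D	GSE21942	MS	9.11E-04	0.489
CLEC2D	GSE43591	MS	7.91E-02	0.24
CLEC2D	GSE16561	IS	2.68E-07	-0.66082
CLEC2D	GSE58294	IS	1.78E-01	0.180726
FOXP1	GSE21942	MS	2.35E-09	1.21
FOXP1	GSE43591	MS	1.17E-02	0.528
FOXP1	GSE16561	IS	4.27E-02	0.149791
FOXP1	GSE58294	IS	1.55E-05	0.339692
LBH	GSE21942	MS	3.52E-02	-0.321
LBH	GSE43591	MS	5.60E-04	-0.553
LBH	GSE16561	IS	5.45E-06	-0.55397
LBH	GSE58294	IS	7.92E-01	0.02761
SLC2A4RG	GSE21942	MS	7.21E-02	-0.205
SLC2A4RG	GSE43591	MS	1.29E-03	-0.332
SLC2A4RG	GSE16561	IS	5.07E-05	-0.24643
SLC2A4RG	GSE58294	IS	3.18E-01	0.07236
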