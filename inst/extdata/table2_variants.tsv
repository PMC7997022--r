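gene	cdna	protein	chrom	pos	ref	alt	consequence	zygosity	sift	polyphen2	mutationtaster	gerp	cadd	condel	ac	an	source
CFAP65	c.A3151G	p.T1023A	2	219886565	T	C	missense	het	0	0.124	1	2.38	18.70	0.763	25	281690	gnomAD_r2_1
RFT1	c.C1450G	p.A463G	3	53156000	C	G	missense	het	0.49	0.001	0	2.53	4.96	0.042	NA	NA	NA
NRXN2	c.G3008A	p.G849D	11	64420000	G	A	missense	het	0	0.973	1	4.93	29.50	0.831	NA	NA	NA
TEP1	c.A1276G	p.Y412C	14	20840000	A	G	missense	het	0.51	0	0	-8.29	0.00	0.050	NA	NA	NA
CCNF	c.G1176C	p.C363S	16	2479000	G	C	missense	het	0.06	0.939	1	5.43	27.30	0.707	NA	NA	NA
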