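##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=CDNA,Number=1,Type=String,Description="cDNA change">
##INFO=<ID=PROT,Number=1,Type=String,Description="Protein change">
##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence class">
##INFO=<ID=ZYG,Number=1,Type=String,Description="Zygosity">
##INFO=<ID=SIFT,Number=1,Type=Float,Description="SIFT score">
##INFO=<ID=PP2,Number=1,Type=Float,Description="PolyPhen-2 score">
##INFO=<ID=MT,Number=1,Type=Float,Description="MutationTaster probability">
##INFO=<ID=GERP,Number=1,Type=Float,Description="GERP++ conservation score">
##INFO=<ID=CADD,Number=1,Type=Float,Description="CADD phred score">
##INFO=<ID=CONDEL,Number=1,Type=Float,Description="Condel score">
##INFO=<ID=AC,Number=1,Type=Integer,Description="Allele count">
##INFO=<ID=AN,Number=1,Type=Integer,Description="Allele number">
##INFO=<ID=SRC,Number=1,Type=String,Description="Frequency source">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
2	219886565	.	T	C	.	PASS	GENE=CFAP65;CDNA=c.A3151G;PROT=p.T1023A;CSQ=missense;ZYG=het;SIFT=0;PP2=0.124;MT=1;GERP=2.38;CADD=18.70;CONDEL=0.763;AC=25;AN=281690;SRC=gnomAD_r2_1
3	53156000	.	C	G	.	PASS	GENE=RFT1;CDNA=c.C1450G;PROT=p.A463G;CSQ=missense;ZYG=het;SIFT=0.49;PP2=0.001;MT=0;GERP=2.53;CADD=4.96;CONDEL=0.042
11	64420000	.	G	A	.	PASS	GENE=NRXN2;CDNA=c.G3008A;PROT=p.G849D;CSQ=missense;ZYG=het;SIFT=0;PP2=0.973;MT=1;GERP=4.93;CADD=29.50;CONDEL=0.831
14	20840000	.	A	G	.	PASS	GENE=TEP1;CDNA=c.A1276G;PROT=p.Y412C;CSQ=missense;ZYG=het;SIFT=0.51;PP2=0;MT=0;GERP=-8.29;CADD=0.00;CONDEL=0.050
16	2479000	.	G	C	.	PASS	GENE=CCNF;CDNA=c.G1176C;PROT=p.C363S;CSQ=missense;ZYG=het;SIFT=0.06;PP2=0.939;MT=1;GERP=5.43;CADD=27.30;CONDEL=0.707
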