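##fileformat=VCFv4.2
##source=kindredscan-fixture
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=EFF,Number=1,Type=String,Description="Effect class">
##INFO=<ID=AF_PANEL1,Number=1,Type=Float,Description="Panel 1 allele frequency">
##INFO=<ID=AF_PANEL2,Number=1,Type=Float,Description="Panel 2 allele frequency">
##INFO=<ID=AF_PANEL3,Number=1,Type=Float,Description="Panel 3 allele frequency">
##INFO=<ID=EVS_AF,Number=1,Type=Float,Description="External exome cohort allele frequency">
##INFO=<ID=KG,Number=0,Type=Flag,Description="Present in 1000 Genomes">
##INFO=<ID=DBSNP,Number=0,Type=Flag,Description="Known dbSNP site">
##INFO=<ID=AC_CTRL,Number=1,Type=Integer,Description="Control alternate allele count">
##INFO=<ID=AN_CTRL,Number=1,Type=Integer,Description="Control called chromosomes">
##INFO=<ID=VQSLOD,Number=1,Type=Float,Description="Variant quality log-odds">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	07	08
1	1000000	.	A	G	.	PASS	GENE=FGENE20;EFF=missense;AF_PANEL1=0.000;AF_PANEL2=0;AF_PANEL3=0;AC_CTRL=0;AN_CTRL=616;VQSLOD=5	GT:DP	0/1:30	0/1:30
1	1050000	rs001050	A	G	.	PASS	GENE=FGENE21;EFF=missense;AF_PANEL1=0.020;AF_PANEL2=0;AF_PANEL3=0;EVS_AF=0.01;KG;DBSNP;AC_CTRL=15;AN_CTRL=612;VQSLOD=4	GT:DP	0/1:30	0/1:30
1	1100000	.	A	G	.	PASS	GENE=FGENE22;EFF=missense;AF_PANEL1=0.000;AF_PANEL2=0;AF_PANEL3=0;AC_CTRL=0;AN_CTRL=616;VQSLOD=0	GT:DP	0/1:30	0/1:30
1	1150000	.	A	G	.	PASS	GENE=FGENE23;EFF=nonsense;AF_PANEL1=0.000;AF_PANEL2=0;AF_PANEL3=0;AC_CTRL=0;AN_CTRL=616;VQSLOD=-2	GT:DP	0/1:30	0/1:30
1	1200000	.	A	G	.	PASS	GENE=FGENE24;EFF=missense;AF_PANEL1=0.000;AF_PANEL2=0;AF_PANEL3=0;AC_CTRL=0;AN_CTRL=616;VQSLOD=6	GT:DP	0/1:3	0/1:30
1	1250000	.	A	G	.	PASS	GENE=FGENE25;EFF=nonsense;AF_PANEL1=0.000;AF_PANEL2=0;AF_PANEL3=0;AC_CTRL=0;AN_CTRL=616;VQSLOD=2	GT:DP	0/1:4	0/1:4
1	1300000	rs001300	A	G	.	PASS	GENE=FGENE26;EFF=missense;AF_PANEL1=0.051;AF_PANEL2=0;AF_PANEL3=0;DBSNP;AC_CTRL=0;AN_CTRL=616;VQSLOD=5	GT:DP	0/1:30	0/1:30
1	1350000	rs001350	A	G	.	PASS	GENE=FGENE27;EFF=missense;AF_PANEL1=0.049;AF_PANEL2=0;AF_PANEL3=0;EVS_AF=0.01;DBSNP;AC_CTRL=5;AN_CTRL=608;VQSLOD=5	GT:DP	0/1:30	0/1:30
1	1400000	.	A	G	.	PASS	GENE=FGENE28;EFF=missense;AF_PANEL1=0.000;AF_PANEL2=0;AF_PANEL3=0;AC_CTRL=0;AN_CTRL=616;VQSLOD=5	GT:DP	0/1:30	./.:30
1	1450000	.	A	G	.	PASS	GENE=FGENE29;EFF=synonymous;AF_PANEL1=0.000;AF_PANEL2=0;AF_PANEL3=0;AC_CTRL=0;AN_CTRL=616;VQSLOD=5	GT:DP	0/1:30	0/1:30
1	1500000	.	A	G	.	PASS	GENE=FGENE30;EFF=intronic;AF_PANEL1=0.000;AF_PANEL2=0;AF_PANEL3=0;AC_CTRL=0;AN_CTRL=616;VQSLOD=5	GT:DP	0/1:30	0/1:30
1	1550000	.	A	G	.	PASS	GENE=FGENE31;EFF=missense;AF_PANEL1=0.000;AF_PANEL2=0;AF_PANEL3=0;AC_CTRL=0;AN_CTRL=616;VQSLOD=5	GT:DP	0/1:30	1/1:30
1	1600000	.	A	G	.	PASS	GENE=FGENE32;EFF=missense;AF_PANEL1=0.000;AF_PANEL2=0;AF_PANEL3=0;AC_CTRL=0;AN_CTRL=616;VQSLOD=5	GT:DP	0/0:30	0/1:30
1	1650000	rs001650	A	G	.	PASS	GENE=FGENE33;EFF=missense;AF_PANEL1=0.000;AF_PANEL2=0;AF_PANEL3=0;EVS_AF=0.06;DBSNP;AC_CTRL=0;AN_CTRL=616;VQSLOD=5	GT:DP	0/1:30	0/1:30
1	1700000	rs001700	A	G	.	PASS	GENE=FGENE34;EFF=missense;AF_PANEL1=0.000;AF_PANEL2=0;AF_PANEL3=0;DBSNP;AC_CTRL=40;AN_CTRL=616;VQSLOD=5	GT:DP	0/1:30	0/1:30
1	2000001	.	A	G	.	PASS	GENE=FGENE40;EFF=nonsense;AF_PANEL1=0.000;AF_PANEL2=0;AF_PANEL3=0;AC_CTRL=0;AN_CTRL=616;VQSLOD=5	GT:DP	0/1:30	0/1:30
1	2200000	.	A	G	.	PASS	GENE=FGENE44;EFF=missense;AF_PANEL1=0.000;AF_PANEL2=0;AF_PANEL3=0;AC_CTRL=0;AN_CTRL=616;VQSLOD=5	GT:DP	1/1:30	1/1:30
1	2500000	.	A	G	.	PASS	GENE=FGENE50;EFF=splice_site;AF_PANEL1=0.000;AF_PANEL2=0;AF_PANEL3=0;AC_CTRL=0;AN_CTRL=616;VQSLOD=5	GT:DP	0/1:30	0/1:30
1	3000000	.	A	G	.	PASS	GENE=FGENE60;EFF=nonsense;AF_PANEL1=0.000;AF_PANEL2=0;AF_PANEL3=0;AC_CTRL=0;AN_CTRL=616;VQSLOD=5	GT:DP	0/1:30	0/1:30
X	500000	.	A	G	.	PASS	GENE=FGENE10;EFF=missense;AF_PANEL1=0.000;AF_PANEL2=0;AF_PANEL3=0;AC_CTRL=0;AN_CTRL=616;VQSLOD=5	GT:DP	1/1:30	1/1:30
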