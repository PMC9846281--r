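name	cls	from	to	strand	anticodon	start_codon	stop_codon	length_published	ign_published
tRNA-Phe	tRNA	1	69	H	GAA			69	0
12S-rRNA	rRNA	70	1022	H				953	2
tRNA-Val	tRNA	1025	1096	H	TAC			72	20
16S-rRNA	rRNA	1117	2756	H				1640	24
tRNA-Leu2	tRNA	2781	2856	H	TAA			76	1
ND1	PCG	2858	3832	H		ATG	TAA	975	4
tRNA-Ile	tRNA	3837	3908	H	GAT			72	-2
tRNA-Gln	tRNA	3907	3977	L	TTG			71	1
tRNA-Met	tRNA	3979	4047	H	CAT			69	0
ND2	PCG	4048	5094	H		ATG	TAG	1047	-2
tRNA-Trp	tRNA	5093	5163	H	TCA			71	2
tRNA-Ala	tRNA	5166	5234	L	TGC			69	1
tRNA-Asn	tRNA	5236	5308	L	GTT			73	2
NCR	noncoding	5311	5342	H				32	-1
tRNA-Cys	tRNA	5342	5407	L	GCA			66	1
tRNA-Tyr	tRNA	5409	5479	L	GTA			71	1
COX1	PCG	5481	7031	H		GTG	TAA	1551	0
tRNA-Ser2	tRNA	7032	7102	L	TGA			71	3
tRNA-Asp	tRNA	7106	7177	H	GTC			72	13
COX2	PCG	7191	7881	H		ATG	T--	691	0
tRNA-Lys	tRNA	7882	7957	H	TTT			76	1
ATP8	PCG	7959	8123	H		ATG	TAA	165	-7
ATP6	PCG	8117	8800	H		ATG	TAA	684	-1
COX3	PCG	8800	9585	H		ATG	TAA	786	-1
tRNA-Gly	tRNA	9585	9656	H	TCC			72	0
ND3	PCG	9657	10007	H		ATG	TAG	351	-2
tRNA-Arg	tRNA	10006	10075	H	TCG			70	0
ND4L	PCG	10076	10372	H		ATG	TAA	297	-7
ND4	PCG	10366	11743	H		ATG	T--	1378	0
tRNA-His	tRNA	11744	11812	H	GTG			69	0
tRNA-Ser1	tRNA	11813	11881	H	GCT			67	1
tRNA-Leu1	tRNA	11883	11955	H	TAG			73	3
ND5	PCG	11959	13782	H		ATG	TAA	1824	-4
ND6	PCG	13779	14300	L		ATG	TAG	522	0
tRNA-Glu	tRNA	14301	14369	L	TTC			69	4
CYTB	PCG	14374	15514	H		ATG	T--	1141	0
tRNA-Thr	tRNA	15515	15586	H	TGT			72	-1
tRNA-Pro	tRNA	15586	15655	L	TGG			70	16
D-LOOP	noncoding	15672	16592	H				921	0
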