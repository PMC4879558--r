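#genome_length=15376
#circular=true
Gene	Class	Direction	Start	End	Size	Anticodon	StartCodon	StopCodon	Intergenic
trnM	tRNA	F	1	67	67	CAT	-	-	0
trnI	tRNA	F	68	132	65	GAT	-	-	-3
trnQ	tRNA	R	130	198	69	TTG	-	-	52
nad2	PCG	F	251	1264	1014	-	ATT	TAA	1
trnW	tRNA	F	1266	1334	69	TCA	-	-	-8
trnC	tRNA	R	1327	1394	68	GCA	-	-	2
trnY	tRNA	R	1397	1461	65	GTA	-	-	2
cox1	PCG	F	1464	2997	1534	-	CGA	T	-1
trnL2(UUR)	tRNA	F	2995	3061	67	TAA	-	-	0
cox2	PCG	F	3062	3743	682	-	ATG	T	0
trnK	tRNA	F	3744	3814	71	CTT	-	-	7
trnD	tRNA	F	3822	3887	66	GTC	-	-	0
atp8	PCG	F	3888	4052	165	-	ATC	TAA	-7
atp6	PCG	F	4046	4723	678	-	ATG	TAA	-1
cox3	PCG	F	4723	5511	789	-	ATG	TAA	2
trnG	tRNA	F	5514	5578	65	TCC	-	-	0
nad3	PCG	F	5579	5932	354	-	ATT	TAA	42
trnA	tRNA	F	5975	6039	65	TGC	-	-	2
trnR	tRNA	F	6042	6104	63	TCG	-	-	6
trnN	tRNA	F	6111	6175	65	GTT	-	-	5
trnS1(AGN)	tRNA	F	6181	6251	71	GCT	-	-	-1
trnE	tRNA	F	6251	6315	65	TTC	-	-	4
trnF	tRNA	R	6320	6386	67	GAA	-	-	-2
nad5	PCG	R	6391	8132	1742	-	ATT	TAA	-2
trnH	tRNA	R	8131	8197	67	GTG	-	-	-2
nad4	PCG	R	8196	9531	1336	-	ATA	TA	-6
nad4L	PCG	R	9526	9812	287	-	ATT	TAA	23
trnT	tRNA	F	9836	9899	64	TGT	-	-	0
trnP	tRNA	R	9900	9963	64	TGG	-	-	7
nad6	PCG	F	9971	10507	537	-	ATA	TAA	-1
cob	PCG	F	10507	11654	1148	-	ATG	TAA	3
trnS2(UCN)	tRNA	F	11658	11723	66	TGA	-	-	30
nad1	PCG	R	11754	12683	930	-	ATT	TAA	4
trnL1(CUN)	tRNA	R	12688	12754	67	TAG	-	-	0
rrnL	rRNA	R	12755	14089	1335	-	-	-	0
trnV	tRNA	R	14090	14155	66	TAC	-	-	0
rrnS	rRNA	R	14156	14942	787	-	-	-	0
CR	control_region	-	14943	15376	434	-	-	-	-
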