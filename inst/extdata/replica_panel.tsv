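gene	contig	start	end
NPM1	chrP	100	207
ABL1	chrP	227	333
ABL1	chrP	353	459
ABL1	chrP	479	585
ABL1	chrP	605	711
AKT1	chrP	731	838
AKT1	chrP	858	964
AKT1	chrP	984	1090
ALK	chrP	1110	1217
ALK	chrP	1237	1344
ALK	chrP	1364	1470
ALK	chrP	1490	1597
APC	chrP	1617	1724
ATM	chrP	1744	1851
ATM	chrP	1871	1977
ATM	chrP	1997	2104
ATM	chrP	2124	2230
ATM	chrP	2250	2356
ATM	chrP	2376	2483
ATM	chrP	2503	2609
ATM	chrP	2629	2736
ATM	chrP	2756	2863
BRAF	chrP	2883	2989
BRAF	chrP	3009	3115
BRAF	chrP	3135	3241
BRAF	chrP	3261	3368
CDH1	chrP	3388	3494
CDH1	chrP	3514	3620
CDH1	chrP	3640	3747
CDH1	chrP	3767	3874
CDH1	chrP	3894	4001
CDH1	chrP	4021	4127
CDH1	chrP	4147	4254
CDKN2A	chrP	4274	4381
CDKN2A	chrP	4401	4507
CDKN2A	chrP	4527	4633
CDKN2A	chrP	4653	4759
CDKN2A	chrP	4779	4886
CSF1R	chrP	4906	5013
CSF1R	chrP	5033	5139
CSF1R	chrP	5159	5265
CSF1R	chrP	5285	5391
CTNNB1	chrP	5411	5517
CTNNB1	chrP	5537	5644
CTNNB1	chrP	5664	5771
CTNNB1	chrP	5791	5897
EGFR	chrP	5917	6024
EGFR	chrP	6044	6151
EGFR	chrP	6171	6278
EGFR	chrP	6298	6404
EGFR	chrP	6424	6530
ERBB2	chrP	6550	6657
ERBB2	chrP	6677	6783
ERBB2	chrP	6803	6909
ERBB2	chrP	6929	7036
ERBB2	chrP	7056	7162
ERBB2	chrP	7182	7288
ERBB4	chrP	7308	7414
ERBB4	chrP	7434	7541
ERBB4	chrP	7561	7668
EZH2	chrP	7688	7794
EZH2	chrP	7814	7921
EZH2	chrP	7941	8048
EZH2	chrP	8068	8174
FBXW7	chrP	8194	8300
FBXW7	chrP	8320	8426
FBXW7	chrP	8446	8552
FBXW7	chrP	8572	8678
FGFR1	chrP	8698	8804
FGFR1	chrP	8824	8930
FGFR1	chrP	8950	9057
FGFR1	chrP	9077	9183
FGFR1	chrP	9203	9310
FGFR1	chrP	9330	9437
FGFR1	chrP	9457	9564
FGFR2	chrP	9584	9691
FGFR2	chrP	9711	9818
FGFR2	chrP	9838	9944
FGFR2	chrP	9964	10070
FGFR2	chrP	10090	10197
FGFR2	chrP	10217	10324
FGFR3	chrP	10344	10451
FGFR3	chrP	10471	10577
FGFR3	chrP	10597	10703
FGFR3	chrP	10723	10830
FLT3	chrP	10850	10957
FLT3	chrP	10977	11084
FLT3	chrP	11104	11210
FLT3	chrP	11230	11337
GNA11	chrP	11357	11464
GNAQ	chrP	11484	11590
GNAQ	chrP	11610	11716
GNAQ	chrP	11736	11843
GNAQ	chrP	11863	11970
GNAQ	chrP	11990	12096
GNAQ	chrP	12116	12223
GNAQ	chrP	12243	12349
GNAS	chrP	12369	12475
GNAS	chrP	12495	12602
GNAS	chrP	12622	12728
GNAS	chrP	12748	12854
GNAS	chrP	12874	12980
GNAS	chrP	13000	13107
HNF1A	chrP	13127	13233
HNF1A	chrP	13253	13359
HRAS	chrP	13379	13485
HRAS	chrP	13505	13611
HRAS	chrP	13631	13737
HRAS	chrP	13757	13864
HRAS	chrP	13884	13990
IDH1	chrP	14010	14116
IDH1	chrP	14136	14242
IDH2	chrP	14262	14368
IDH2	chrP	14388	14495
IDH2	chrP	14515	14621
IDH2	chrP	14641	14747
IDH2	chrP	14767	14873
JAK2	chrP	14893	14999
JAK2	chrP	15019	15125
JAK2	chrP	15145	15251
JAK3	chrP	15271	15377
JAK3	chrP	15397	15504
JAK3	chrP	15524	15630
KDR	chrP	15650	15757
KDR	chrP	15777	15883
KDR	chrP	15903	16009
KDR	chrP	16029	16136
KIT	chrP	16156	16262
KIT	chrP	16282	16388
KIT	chrP	16408	16514
KIT	chrP	16534	16641
KRAS	chrP	16661	16768
KRAS	chrP	16788	16894
KRAS	chrP	16914	17020
KRAS	chrP	17040	17147
KRAS	chrP	17167	17273
MET	chrP	17293	17400
MET	chrP	17420	17527
MET	chrP	17547	17653
MET	chrP	17673	17780
MLH1	chrP	17800	17906
MLH1	chrP	17926	18033
MLH1	chrP	18053	18160
MLH1	chrP	18180	18286
MLH1	chrP	18306	18413
MPL	chrP	18433	18539
MPL	chrP	18559	18666
MPL	chrP	18686	18793
MPL	chrP	18813	18919
NOTCH1	chrP	18939	19046
NOTCH1	chrP	19066	19172
NRAS	chrP	19192	19298
NRAS	chrP	19318	19424
NRAS	chrP	19444	19550
NRAS	chrP	19570	19677
NRAS	chrP	19697	19804
NRAS	chrP	19824	19931
PDGFRA	chrP	19951	20057
PDGFRA	chrP	20077	20183
PDGFRA	chrP	20203	20309
PDGFRA	chrP	20329	20436
PDGFRA	chrP	20456	20563
PDGFRA	chrP	20583	20690
PIK3CA	chrP	20710	20816
PIK3CA	chrP	20836	20942
PTEN	chrP	20962	21068
PTEN	chrP	21088	21195
PTEN	chrP	21215	21322
PTEN	chrP	21342	21449
PTEN	chrP	21469	21575
PTEN	chrP	21595	21701
PTEN	chrP	21721	21827
PTEN	chrP	21847	21954
PTEN	chrP	21974	22080
PTPN11	chrP	22100	22207
RB1	chrP	22227	22333
RB1	chrP	22353	22459
RB1	chrP	22479	22585
RET	chrP	22605	22711
RET	chrP	22731	22838
RET	chrP	22858	22964
RET	chrP	22984	23090
RET	chrP	23110	23216
SMAD4	chrP	23236	23343
SMAD4	chrP	23363	23469
SMAD4	chrP	23489	23596
SMAD4	chrP	23616	23723
SMARCB1	chrP	23743	23849
SMARCB1	chrP	23869	23975
SMO	chrP	23995	24101
SMO	chrP	24121	24228
SMO	chrP	24248	24354
SMO	chrP	24374	24480
SMO	chrP	24500	24606
SMO	chrP	24626	24732
SMO	chrP	24752	24858
SRC	chrP	24878	24984
SRC	chrP	25004	25110
SRC	chrP	25130	25236
STK11	chrP	25256	25362
STK11	chrP	25382	25488
STK11	chrP	25508	25615
STK11	chrP	25635	25742
STK11	chrP	25762	25869
STK11	chrP	25889	25995
TP53	chrP	26015	26121
VHL	chrP	26141	26247
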