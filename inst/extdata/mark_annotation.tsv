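locus	snp	haplotype	h3k27ac	h3k4me1	gro_resting	gro_activated
PTPN22	rs6679677	chr1:113,761,186-113,834,946	+	+	+	+
ATP882-IL6R	rs11265608	chr1:154,319,242-154,406,893	+	+	+	+
STAT4	rs10174238	chr2:191,079,016-191,108,308	-	+	-	-
IL2-21	rs1479924	chr4:122,151,854-122,619,603	+	+	+	+
ANKRD55	rs71624119	chr5:56,141,024-56,146,422	-	+	–	+
ERAP2-LNPEP	rs27290	chr5:96,884,383-97,038,046	+	+	+	+
C5orf56-IRF1	rs4705862	chr5:132,477,527-132,496,822	+	+	–	–
HLA-DQB1-DQA2	rs7775055	chr6:32,422,420-32,712,215	+	+	–	–
IL2RA	rs7909519	chr10:6,028,313-6,055,320	-	+	+	+
SH2B3-ATXN2	rs3184504	chr12:111,395,984-111,645,358	+	+	+	+
ZFP36L1	rs12434551	chr14:68,784,174-68,794,755	+	+	–	+
PTPN2	rs2847293	chr18:12,774,327-12,809,341	-	-	+	+
TYK2	rs34536443	chr19:10,317,045-10,381,598	+	+	-	+
RUNX1	rs9979383	chr21:35,323,611-35,365,944	-	-	-	-
UBE2L3	rs2266959	chr22:21,556,931-21,628,971	+	+	-	-
IL2RB	rs2284033	chr22:37,135,077-37,141,474	-	-	-	-
TIMMDC1-CD80	rs4688011	chr3:119,406,355-119,529,051	+	+	-	-
JAK1	rs10889504	chr1:64,924,820-64,975,081	+	+	+	+
PRR9-LOR	rs873234	chr1:153,249,128-153,270,022	-	+	+	+
PTH1R	rs1138518	chr3:46,889,988-46,932,682	+	+	-	+
ILDR1-CD86	rs111700762	chr3:122,023,892-122,102,059	+	+	+	+
LINC-00951	rs10807228	chr6:40,198,646-40,261,171	-	-	-	-
AHI1-LINC-00271	rs9321502	chr6:135,303,673-135,371,709	+	+	-	–
HBP1	rs111865019	chr7:107,156,092-107,390,877	+	+	+	+
WDFY4	rs1904603	chr10:48,776,493-48,805,795	+	+	-	+
RNF215	rs5753109	chr22:30,289,571-30,403,731	+	+	-	-
LTBR	rs2364480	chr12:6,384,185-6,402,830	+	+	-	-
IL6	rs7808122	chr7:22,729,088-22,771,765	-	-	-	-
COG6	rs7993214	chr13:39,726,191-39,794,464	-	-	-	-
13q14	rs34132030	chr13:42,481,900-42,492,387	-	-	-	-
CCR1-CCR3	rs79893749	chr3:46,141,688-46,420,292	+	+	-	-
PRRL5	rs4755450	chr11:36,314,713-36,354,471	-	+	-	-
PRM1-RM12	rs66718203	chr16:11,278,799-11,352,790	+	+	-	-
RUNX3	rs4648881	chr1:24,870,664-24,884,324	-	+	-	-
JAZF1	rs10280937	chr7:28,114,765-28,207,370	+	+	-	-
AFF3-LONRF2	rs6740838	chr2:100,196,869-100,221,105	-	+	-	-
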