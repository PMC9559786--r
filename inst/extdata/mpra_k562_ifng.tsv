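locus	context	region	gro_resting	gro_activated
PTPN22	intronic	chr1:113,800,033-113,807,167	–	–
IL6RA/ATP8B2	intronic	chr1:154,312,194-154,313,462	+	+
IL6RA/ATP8B2	intergenic	chr1:154,351,989-154,356,495	+	+
IL10	intronic	chr1:206,768,609-206,772,399	–	–
STAT4	intronic	chr2:191,041,359-191,043,004	–	–
CCR1/CCR3	intergenic	chr3:46,297,890-46,306,532	–	–
TIMMDC1	intronic	chr3:119,394,863-119,412,040	+	+
LNPEP/ERAP2	intergenic	chr5:96,920,167-96,924,958	–	–
LNPEP/ERAP2	intronic	chr5:96,995,366-96,995,917	–	–
IRF1	intergenic	chr5:132,490,541-132,492,289	+	–
TRAF1	intergenic	chr9:120,941,159-120,947,188	+	+
IL2RA	intronic	chr10:6,040,089-6,040,684	–	–
ZFP36L1	intronic	chr14:68,794,471-68,796,262	–	–
ZFP36L1	intergenic	chr14:68,800,391-68,801,105	–	–
RM12	intronic	chr16:11,283,902-11,284,672	–	–
PTPN2	intergenic	chr18:12,775,801-12,776,691	–	–
PTPN2	intronic	chr18:12,860,578-12,861,552	+	+
TYK/ICAM3	intronic	chr19:10,333,403-10,334,831	+	+
TYK/ICAM3	intergenic	chr19:10,347,076-10,348,009	+	+
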