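locus	context	region	gro_resting	gro_activated
IL6R-ATP8B2	intergenic	chr1:154,312,218-154,401,421	+	+
IL10	intronic	chr1:206,769,578-206,772,118	–	–
STAT4	intronic	chr2:191,037,761-191,039,047	–	–
CCR2	intergenic	chr3:46,321,182-46,323,267	+	+
TIMMDC1	intronic	chr3:119,506,272-119,508,916	–	–
ERAP2/LNPEP	intergenic	chr5:96,929,602-96,933,140	–	–
ERAP2/LNPEP	intronic	chr5:96,967,226-96,969,507	–	–
IRF1	intergenic	chr5:132,491,627-132,499,135	+	+
JAZF1	intronic	chr7:28,124,680-28,152,184	+	+
IL6	intronic	chr7:22,725,624-22,727,193	–	–
TRAF1	intronic	chr9:120,921,603-120,923,567	+	+
TRAF1	intergenic	chr9:120,929,875-120,936,755	–	+
IL2RA	intronic	chr10:6,047,090-6,055,660	–	–
LTBR	intronic	chr12:6,384,706-6,385,089	–	–
TNFSF1	intergenic	chr13:42,476,952-42,480,776	–	–
ZFPl36F1	intronic	chr14:68,793,403-68,794,934	–	–
RMI2	intronic	chr16:11,348,423-11,351,691	+	+
TYK2	intergenic	chr19:10,345,527-10,347,710	+	+
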