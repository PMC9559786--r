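snp	locus	gene	p_value	p_threshold
rs4688012	TIMMCD1	TIMMCD1	0.00014	0.00023
rs11581043	IL6R/ATP8B2	ATP8B2	2.2e-11	0.00018
rs10739578	TRAF1	C5	4.0e-9	0.0002
rs10739578	TRAF1	PSMD5	0.00013	0.00021
rs10739578	TRAF1	PSMD5-AS1	3.4e-36	0.0002
rs10739578	TRAF1	TRAF1	1.8E-11	0.00022
rs2109896	TRAF1	C5	1.5E-08	0.0002
rs2109896	TRAF1	PSMD5	0.000018	0.00021
rs2109896	TRAF1	PSMD5-AS1	5.2e-42	0.0002
rs7859805	TRAF1	C5	4.1e-08	0.00022
rs7859805	TRAF1	PSMD5	0.000017	0.00021
rs7859805	TRAF1	PSMD5-AS1	4.8e-40	0.0002
rs10985080	TRAF1	C5	8.5e-09	0.0002
rs10985080	TRAF1	PHF19	0.000068	0.00021
rs10985080	TRAF1	PSMD5	0.000051	0.00021
rs10985080	TRAF1	PSMD5-AS1	4.5e-43	0.0002
rs10985080	TRAF1	TRAF1	1.3e-08	0.00022
rs2549004	IRF1	C5orf56	1.3e-14	0.00024
rs2549004	IRF1	SLC22A5	9.9e-07	0.00028
rs2549007	IRF1	C5orf56	9.3e-15	0.00024
rs2549007	IRF1	SLC22A5	0.0000012	0.00028
rs2549009	IRF1	C5orf56	6.0e-14	0.00024
rs2549009	IRF1	SLC22A5	1.2e-07	0.00028
rs2706385	IRF1	C5orf56	7.5e-16	0.00025
rs2706385	IRF1	SLC22A5	0.0000023	0.00028
rs2706386	IRF1	C5orf56	5.3e-16	0.00024
rs2706386	IRF1	SLC22A5	0.0000011	0.00028
rs41525648	IRF1	C5orf56	0.0000014	0.00024
rs41525648	IRF1	SLC22A5	4.0e-14	0.00028
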