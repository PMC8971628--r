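snp	chrom	pos	ref	alt	gene	exac_eas_over_all	g1000_eas_over_all	or_exac	or_converge	exac_all	exac_eas	exac_nonpsych_all	exac_nonpsych_eas	g1000_all	g1000_eas	deleteriousness
rs2293239	chr10	49739806	C	T	OGDHL	13.9333	4.9603	2.1815	1.2602	0.0015	0.0209	0.0012	0.0183	0.0042	0.0208	9
rs201457933	chr15	81300079	C	G	IL16	12.7500	4.9766	NA	0.979	0.0016	0.0204	0.0013	0.0171	0.0032	0.0159	2
rs79499419	chr18	74126069	C	T	FBXO15	13.3000	4.4571	3.0087	0.8722	0.0010	0.0133	0.0007	0.0098	0.0020	0.0089	1
rs41298838	chr22	19765921	A	G	TBX1	53.2105	4.8633	42.7604	1.1531	0.0019	0.1011	0.0010	0.1250	0.0090	0.0437	4
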