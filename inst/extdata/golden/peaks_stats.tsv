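name	contig	start	end	summit	length	fold_enrichment	avg_coverage	pearson_r	neglog10_p
peak_1	chr1	182315	182542	182431	227	13.88443	253031.03951	0.69948	39.40842
peak_2	chr1	185535	185752	185655	217	13.64586	259528.42377	0.65756	34.90103
peak_3	chr1	187552	187775	187642	223	13.45011	257770.67753	0.63834	34.90020
peak_4	chr1	775232	775451	775325	219	13.28477	258658.95970	0.59927	33.40893
peak_5	chr1	588041	588280	588154	239	13.28393	247326.96149	0.70776	39.40842
peak_6	chr1	424546	424778	424663	232	13.16644	252535.77899	0.68498	40.70511
peak_7	chr1	385139	385376	385258	237	13.12355	248027.42439	0.66359	32.26618
peak_8	chr1	486954	487188	487068	234	13.09355	246802.35817	0.67532	39.36878
peak_9	chr1	133829	134063	133927	234	13.08732	249419.76549	0.66751	33.53820
peak_10	chr1	153503	153737	153619	234	12.99015	248653.69505	0.69091	35.08572
peak_11	chr1	23840	24073	23964	233	12.90794	246515.21875	0.65647	32.87157
peak_12	chr1	457960	458206	458089	246	12.82118	244661.40929	0.70185	34.97920
peak_13	chr1	134855	135082	134967	227	12.73787	249148.37857	0.62966	36.35236
peak_14	chr1	273716	273945	273829	229	12.67966	246385.31255	0.61653	34.96442
peak_15	chr1	92549	92790	92675	241	12.64298	246266.21482	0.67607	39.40842
peak_16	chr1	15383	15628	15516	245	12.57417	244440.56823	0.71416	40.79308
peak_17	chr1	894910	895151	895020	241	12.41420	245336.44054	0.72637	33.51771
peak_18	chr1	173173	173406	173294	233	12.21352	251708.38721	0.72013	34.98562
peak_19	chr1	204423	204651	204543	228	12.21024	252445.40770	0.67794	33.18071
peak_20	chr1	8463	8707	8571	244	12.10248	240115.98658	0.69256	33.62738
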