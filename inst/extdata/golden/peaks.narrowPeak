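chr1	182315	182542	peak_1	394	.	13.88443	39.40842	-1	116
chr1	185535	185752	peak_2	349	.	13.64586	34.90103	-1	120
chr1	187552	187775	peak_3	349	.	13.45011	34.90020	-1	90
chr1	775232	775451	peak_4	334	.	13.28477	33.40893	-1	93
chr1	588041	588280	peak_5	394	.	13.28393	39.40842	-1	113
chr1	424546	424778	peak_6	407	.	13.16644	40.70511	-1	117
chr1	385139	385376	peak_7	323	.	13.12355	32.26618	-1	119
chr1	486954	487188	peak_8	394	.	13.09355	39.36878	-1	114
chr1	133829	134063	peak_9	335	.	13.08732	33.53820	-1	98
chr1	153503	153737	peak_10	351	.	12.99015	35.08572	-1	116
chr1	23840	24073	peak_11	329	.	12.90794	32.87157	-1	124
chr1	457960	458206	peak_12	350	.	12.82118	34.97920	-1	129
chr1	134855	135082	peak_13	364	.	12.73787	36.35236	-1	112
chr1	273716	273945	peak_14	350	.	12.67966	34.96442	-1	113
chr1	92549	92790	peak_15	394	.	12.64298	39.40842	-1	126
chr1	15383	15628	peak_16	408	.	12.57417	40.79308	-1	133
chr1	894910	895151	peak_17	335	.	12.41420	33.51771	-1	110
chr1	173173	173406	peak_18	350	.	12.21352	34.98562	-1	121
chr1	204423	204651	peak_19	332	.	12.21024	33.18071	-1	120
chr1	8463	8707	peak_20	336	.	12.10248	33.62738	-1	108
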