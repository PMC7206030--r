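gene_id	direction	fold	log2fc	p
gene014	down	0.56434	-0.82536	0.0047408
gene015	down	0.45371	-1.14015	0.0012751
gene016	down	0.45581	-1.13348	0.0030653
gene018	down	0.48800	-1.03505	0.0019734
xgene0013	down	0.44405	-1.17122	0.010215
xgene0014	down	0.45868	-1.12444	0.0070391
xgene0015	down	0.41145	-1.28120	0.0127
xgene0016	down	0.46226	-1.11322	0.0058883
xgene0017	down	0.47472	-1.07485	0.031318
xgene0041	down	0.56787	-0.81636	0.0068467
xgene0042	down	0.56274	-0.82946	0.020727
xgene0043	down	0.54885	-0.86552	0.010402
xgene0044	down	0.45283	-1.14297	0.0034448
xgene0045	down	0.45020	-1.15136	0.0035542
xgene0046	down	0.45698	-1.12981	0.0097953
xgene0047	down	0.47341	-1.07885	0.0094933
xgene0048	down	0.50248	-0.99286	0.047517
xgene0051	down	0.50782	-0.97762	0.015665
xgene0052	down	0.49624	-1.01090	0.0062124
xgene0054	down	0.42175	-1.24554	0.0017654
xgene0055	down	0.50921	-0.97367	0.00028953
gene003	up	2.17241	1.11930	0.010028
gene004	up	1.98791	0.99125	0.011516
xgene0001	up	1.96711	0.97607	0.0068745
xgene0003	up	2.11846	1.08302	4.6327e-05
xgene0004	up	2.12884	1.09007	0.01346
xgene0005	up	1.94932	0.96297	0.022413
xgene0026	up	1.78405	0.83515	0.011915
xgene0027	up	3.00735	1.58849	0.00016132
xgene0028	up	1.93723	0.95399	0.0011024
xgene0029	up	1.92926	0.94805	0.0032109
xgene0030	up	1.77823	0.83044	0.01224
xgene0032	up	1.88644	0.91566	0.00074633
xgene0033	up	1.84534	0.88389	0.025742
xgene0034	up	1.89397	0.92141	0.01015
xgene0035	up	2.12030	1.08427	0.006958
xgene0036	up	1.83865	0.87865	0.0012327
xgene0037	up	2.12903	1.09020	0.014296
xgene0038	up	1.87959	0.91042	0.010216
xgene0040	up	2.19025	1.13110	0.0037763
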