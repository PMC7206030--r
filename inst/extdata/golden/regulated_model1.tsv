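gene_id	direction	fold	log2fc	p
gene014	down	0.50048	-0.99860	0.00035903
gene016	down	0.58235	-0.78005	0.00775
gene017	down	0.47704	-1.06782	0.0024218
gene018	down	0.44657	-1.16304	0.0059559
gene019	down	0.47282	-1.08065	0.018785
gene020	down	0.42850	-1.22263	0.0050835
gene021	down	0.47634	-1.06993	0.0042068
gene022	down	0.54999	-0.86251	0.00075738
gene023	down	0.51461	-0.95845	0.0077295
gene024	down	0.53007	-0.91575	0.0096196
gene025	down	0.42315	-1.24075	0.0024091
xgene0014	down	0.36964	-1.43580	5.6047e-05
xgene0015	down	0.38825	-1.36496	0.01648
xgene0016	down	0.50250	-0.99281	0.0099055
xgene0017	down	0.55708	-0.84404	0.0070883
xgene0018	down	0.53975	-0.88965	0.0028372
xgene0019	down	0.52756	-0.92259	0.0094961
xgene0020	down	0.53278	-0.90838	0.039023
xgene0021	down	0.43495	-1.20107	0.0012558
xgene0022	down	0.51755	-0.95023	0.022523
xgene0023	down	0.52840	-0.92030	0.018258
xgene0024	down	0.48709	-1.03774	0.0083153
xgene0025	down	0.43923	-1.18696	0.0020074
gene001	up	1.97271	0.98018	0.025474
gene002	up	2.18365	1.12674	0.00018178
gene003	up	1.90167	0.92727	9.0736e-06
gene004	up	2.53527	1.34214	0.0028782
gene005	up	2.03721	1.02659	0.02454
gene006	up	2.37588	1.24846	0.0046491
gene008	up	2.56531	1.35913	0.0022603
gene009	up	1.88485	0.91445	0.0035645
gene010	up	1.84200	0.88127	0.014468
gene011	up	1.77731	0.82970	0.00033765
gene012	up	2.31771	1.21270	0.0032153
gene013	up	2.27801	1.18778	0.0009181
xgene0002	up	2.22915	1.15650	0.00019183
xgene0003	up	2.00180	1.00129	0.027601
xgene0005	up	2.31893	1.21346	0.00040322
xgene0006	up	1.73093	0.79155	0.0034872
xgene0008	up	2.44002	1.28689	0.0005929
xgene0010	up	2.01762	1.01266	0.00062076
xgene0011	up	1.75834	0.81421	0.021314
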