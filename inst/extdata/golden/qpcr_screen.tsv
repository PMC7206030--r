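target	log2fc_model1	log2fc_model2	candidate
t01	1.75445	1.90332	TRUE
t02	2.14525	2.05898	TRUE
t03	1.72496	1.77441	TRUE
t04	1.91233	1.91755	TRUE
t05	1.94880	2.01344	TRUE
t06	2.08906	1.87805	TRUE
t07	1.75325	1.87820	TRUE
t08	1.98851	2.13750	TRUE
t09	1.89553	1.76861	TRUE
t10	1.67654	2.23481	TRUE
t11	1.93291	0.06656	FALSE
t12	1.90092	-0.00588	FALSE
t13	1.92556	-0.18774	FALSE
t14	1.86317	-0.24909	FALSE
t15	1.96500	0.04155	FALSE
t16	-0.25022	1.93447	FALSE
t17	-0.36739	1.93480	FALSE
t18	0.09572	1.87690	FALSE
t19	-0.09624	1.92374	FALSE
t20	-0.07259	1.92631	FALSE
t21	0.05395	0.08001	FALSE
t22	0.05564	-0.05877	FALSE
t23	0.03551	-0.03635	FALSE
t24	0.14766	-0.15374	FALSE
t25	-0.04547	0.16614	FALSE
t26	-0.14468	-0.10823	FALSE
t27	-0.12351	-0.14933	FALSE
t28	-0.04133	0.09279	FALSE
t29	0.19324	-0.07298	FALSE
t30	-0.03427	-0.01175	FALSE
t31	0.02903	-0.45366	FALSE
t32	0.25025	-0.15671	FALSE
t33	-0.20076	0.15373	FALSE
t34	-0.06705	-0.15095	FALSE
t35	-0.03874	-0.09009	FALSE
t36	-0.00387	-0.03548	FALSE
t37	ND	ND	FALSE
t38	ND	ND	FALSE
t39	ND	ND	FALSE
t40	ND	ND	FALSE
t41	ND	ND	FALSE
t42	ND	ND	FALSE
t43	ND	ND	FALSE
t44	ND	ND	FALSE
t45	ND	ND	FALSE
t46	ND	ND	FALSE
t47	ND	ND	FALSE
t48	ND	ND	FALSE
t49	ND	ND	FALSE
t50	ND	ND	FALSE
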