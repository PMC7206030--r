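name	contig	start	end	summit	category	genes
peak_1	chr1	182315	182542	182431	exon	gene022
peak_2	chr1	185535	185752	185655	intron	gene023
peak_3	chr1	187552	187775	187642	promoter	gene023
peak_4	chr1	775232	775451	775325	promoter	gene097
peak_5	chr1	588041	588280	588154	promoter	gene073
peak_6	chr1	424546	424778	424663	intergenic	
peak_7	chr1	385139	385376	385258	promoter	gene048,gene049
peak_8	chr1	486954	487188	487068	intergenic	
peak_9	chr1	133829	134063	133927	promoter	gene014
peak_10	chr1	153503	153737	153619	promoter	gene017,gene018
peak_11	chr1	23840	24073	23964	promoter	gene003
peak_12	chr1	457960	458206	458089	exon	gene058
peak_13	chr1	134855	135082	134967	promoter	gene014
peak_14	chr1	273716	273945	273829	intergenic	
peak_15	chr1	92549	92790	92675	promoter	gene012
peak_16	chr1	15383	15628	15516	promoter	gene002
peak_17	chr1	894910	895151	895020	promoter	gene109
peak_18	chr1	173173	173406	173294	promoter	gene020,gene021
peak_19	chr1	204423	204651	204543	intron	gene025
peak_20	chr1	8463	8707	8571	promoter	gene001
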