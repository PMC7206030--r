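peak_id	max_t_fraction	positive
peak_chr1_182315_182542	0.85714	TRUE
peak_chr1_185535_185752	0.47619	FALSE
peak_chr1_187552_187775	0.52381	FALSE
peak_chr1_133829_134063	0.90476	TRUE
peak_chr1_153503_153737	0.95238	TRUE
peak_chr1_23840_24073	0.80952	TRUE
peak_chr1_134855_135082	0.47619	FALSE
peak_chr1_92549_92790	0.47619	FALSE
peak_chr1_15383_15628	0.95238	TRUE
peak_chr1_173173_173406	0.47619	FALSE
peak_chr1_204423_204651	0.90476	TRUE
peak_chr1_8463_8707	0.47619	FALSE
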