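metric	value
regulated_model1_n	42
regulated_model2_n	40
overlap_observed	11
overlap_expected	0.84000
overlap_fraction_A	0.02100
overlap_fraction_B	0.02000
overlap_p	1.3034e-10
occupied_and_regulated	12
regulated_total	42
fraction_occupied_regulated	0.28571
fraction_occupied_other	0.00306
occupancy_odds_ratio	130.13333
occupancy_p	2.2809e-17
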