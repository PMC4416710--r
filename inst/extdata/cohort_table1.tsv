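variable	n_a	mean_a	sd_a	n_b	mean_b	sd_b
age	31	33.45	12	31	38.81	9.76
reading_test_JART	31	113.33	8.51	31	109.29	10.19
semantic_successful_trials	31	29.19	1.51	31	27.81	3.12
semantic_reaction_time_s	31	1.28	0.32	31	1.50	0.33
phonological_successful_trials	31	29.19	1.54	31	26.58	2.86
phonological_reaction_time_s	31	1.39	0.36	31	1.65	0.34
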