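round	phred_min	gr_min	maf_min	maf_max	design_min	flank_len	first_set	second_set
1	10	0.45	0.05	0.50	0.60	40	45156	17148
2	10	0.45	0.05	0.50	0.60	35	1319	1876
3	10	0.15	0.04	0.50	0.60	40	4027	6734
4	10	0.15	0.04	0.50	0.60	35	320	628
5	10	0.15	0.01	0.039	0.60	40	829	1821
6	10	0.15	0.01	0.039	0.60	35	121	222
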