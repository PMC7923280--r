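lower_kbp	upper_kbp	study_count	array_count
0	10	4683	4510
10	20	32282	29070
20	30	21145	19146
30	40	10848	11069
40	50	5999	6682
50	60	2770	3011
60	70	1075	1285
70	80	541	696
80	90	302	366
90	100	210	243
100	200	315	375
200	300	29	35
300	400	10	10
400	500	3	3
500	600	6	5
600	700	0	1
700	800	1	1
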