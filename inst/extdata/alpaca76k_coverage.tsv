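group	n_snps	n_fragments	mean_interval	covered_bp	reference_bp	percent_covered
localized	59297	38165	26992	1525673735	1602467523	95.21
unassigned	17211	12491	25160	393461101	517133374	76.09
total	76508	50656	26580	1919134836	2119600897	90.54
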