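set	study_count	array_count
first	51772	49282
second	28429	26924
candidate	302	302
controls	.	100
duplicate_controls	.	302
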