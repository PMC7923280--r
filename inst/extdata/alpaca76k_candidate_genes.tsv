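gene	source	count
KRT	novel	205
KRTAP	novel	56
MC1R	novel	1
ASIP	novel	2
KIT	novel	18
TYRP1	novel	1
KRT	literature	16
MC1R	literature	1
TYRP1	literature	2
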