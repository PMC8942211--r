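name	a	b	c	d
missense_synonymous	41691	20282	176888	92314
peptide	287	58706	254	285859
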