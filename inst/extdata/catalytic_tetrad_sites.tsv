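reference_position	expected_residue
71	D
76	Y
103	K
152	H
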