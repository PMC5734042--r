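species	score	length	rank
Phanerochaete_carnosa	412	987	1
Phanerochaete_carnosa	203	512	2
Dichomitus_squalens	59	900	1
Trametes_versicolor	188	150	1
Trametes_versicolor	151	402	2
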