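name	recognition	cut_top	cut_bottom	overhang	cutting_fraction
BamHI	GGATCC	1	5	5prime	1
NotI	GCGGCCGC	2	6	5prime	1
SrfI	GCCCGGGC	4	4	blunt	1
AsiSI	GCGATCGC	5	3	3prime	1
I-SceI	TAGGGATAACAGGGTAAT	9	5	3prime	1
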