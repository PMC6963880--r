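name	recognition	cut_top	cut_bottom
PleI	GAGTC	4	5
MlyI	GAGTC	5	5
EcoRI	GAATTC	-5	-5
HindIII	AAGCTT	-5	-5
EcoRV	GATATC	-3	-3
AluI	AGCT	-2	-2
MboI	GATC	-4	-4
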