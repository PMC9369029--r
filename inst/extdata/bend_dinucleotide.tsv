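dinucleotide	value
AA	0.35
AC	0.25
AG	0.20
AT	0.75
CA	0.60
CC	0.15
CG	0.45
CT	0.20
GA	0.20
GC	0.30
GG	0.15
GT	0.25
TA	1.00
TC	0.20
TG	0.60
TT	0.35
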