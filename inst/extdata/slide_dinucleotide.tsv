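dinucleotide	value
AA	1
AC	0
AG	0
AT	1
CA	0
CC	0
CG	0
CT	0
GA	0
GC	0
GG	0
GT	0
TA	1
TC	0
TG	0
TT	1
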