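pos	A	C	G	T
1	0	0	0	0
2	-0.693147180559945	-0.693147180559945	-0.693147180559945	0.916290731874155
3	-0.693147180559945	0.916290731874155	-0.693147180559945	-0.693147180559945
4	0.916290731874155	-0.693147180559945	-0.693147180559945	-0.693147180559945
5	-0.693147180559945	0.916290731874155	-0.693147180559945	-0.693147180559945
6	-0.693147180559945	-0.693147180559945	-0.693147180559945	0.916290731874155
7	0.916290731874155	-0.693147180559945	-0.693147180559945	-0.693147180559945
8	-0.693147180559945	-0.693147180559945	-0.693147180559945	0.916290731874155
9	0.916290731874155	-0.693147180559945	-0.693147180559945	-0.693147180559945
10	-0.693147180559945	-0.693147180559945	-0.693147180559945	0.916290731874155
11	0.916290731874155	-0.693147180559945	-0.693147180559945	-0.693147180559945
12	-0.693147180559945	-0.693147180559945	-0.693147180559945	0.916290731874155
13	0.916290731874155	-0.693147180559945	-0.693147180559945	-0.693147180559945
14	-0.693147180559945	-0.693147180559945	0.916290731874155	-0.693147180559945
15	0	0	0	0
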