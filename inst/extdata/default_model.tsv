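key	value
window_w	15
c0	0
c1	1
c2	1
c3	1
epsilon	0.5
scan_both_strands	FALSE
pwm_file	tata_pwm.tsv
slide_scale_file	slide_dinucleotide.tsv
bend_scale_file	bend_dinucleotide.tsv
a1	1.1
b1	0.9
a2	7.0
b2	0.6
alpha	0.05
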