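dataset_id	n	r	p_r	R	p_R	tau	p_tau	gamma	p_gamma	intercept	slope
1	20	0.870721	5.93643e-07	0.648853	0.00196764	0.450943	0.00574258	0.454545	0.000461149	1.00012	0.973182
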