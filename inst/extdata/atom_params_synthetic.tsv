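residue	type	etr
*	Csp3	-0.012
*	Csp2	-0.01
*	Hnc	-0.008
*	Hc	0.012
*	O	0.022
*	N	0.018
*	S	-0.01
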