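# Published antisense oligos used for Gag knockdown (name, 5'-3' sequence, chemistry)
bik1_lna	GGTGACGACTGGCAAAGATGAC	LNA
bik1_mo	GTCTTTGGGGTGAGCCATGTTTTGC	MO
bik2_mo	GGGAAGACCTATAACTGACACTGAC	MO
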