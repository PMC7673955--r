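residue_index	residue	score
1	M	0.658
2	A	0.663
3	K	0.472
4	L	0.97
5	V	0.402
6	S	0.85
7	T	0.757
8	K	0.533
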