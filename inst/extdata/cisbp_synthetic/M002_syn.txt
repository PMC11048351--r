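Pos	A	C	G	U
1	0	0	0	1
2	1	0	0	0
3	0	0	1	0
4	0	0	1	0
5	0	0	1	0
6	1	0	0	0
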