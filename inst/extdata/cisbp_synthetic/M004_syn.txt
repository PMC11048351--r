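Pos	A	C	G	U
1	0.077709	0.020685	0.853004	0.048602
2	0.841323	0.055257	0.093771	0.009649
3	0.118457	0.560920	0.189227	0.131396
4	0.436271	0.230656	0.126882	0.206191
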