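Pos	A	C	G	U
1	0.406990	0.372165	0.161308	0.059537
2	0.198871	0.012705	0.724623	0.063801
3	0.188430	0.152400	0.019756	0.639414
4	0.422182	0.285495	0.085346	0.206977
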