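Pos	A	C	G	U
1	0.248191	0.331766	0.337893	0.082150
2	0.618347	0.161833	0.063801	0.156019
3	0.073601	0.041541	0.552526	0.332332
4	0.107301	0.433107	0.020224	0.439368
5	0.176611	0.543318	0.049938	0.230133
6	0.076051	0.431594	0.155228	0.337127
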