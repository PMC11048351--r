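Pos	A	C	G	U
1	0.332407	0.083809	0.338679	0.245105
2	0.761613	0.016256	0.221790	0.000341
3	0.181706	0.360454	0.206592	0.251248
4	0.365156	0.473299	0.095031	0.066514
5	0.075152	0.471726	0.434505	0.018617
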