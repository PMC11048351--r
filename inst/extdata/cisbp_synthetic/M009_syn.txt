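Pos	A	C	G	U
1	0.121176	0.132205	0.255825	0.490794
2	0.071333	0.307488	0.348448	0.272731
3	0.322303	0.559152	0.014624	0.103921
4	0.055524	0.089631	0.510130	0.344715
5	0.554009	0.008672	0.265880	0.171439
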