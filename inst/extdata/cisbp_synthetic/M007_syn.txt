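Pos	A	C	G	U
1	0.086971	0.333849	0.506566	0.072614
2	0.404772	0.161698	0.229748	0.203782
3	0.859555	0.012693	0.087574	0.040178
4	0.489545	0.067299	0.132183	0.310973
5	0.755862	0.074605	0.030576	0.138957
6	0.120722	0.035956	0.221630	0.621692
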