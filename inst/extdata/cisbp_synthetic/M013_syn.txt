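Pos	A	C	G	U
1	0.214031	0.144341	0.433684	0.207944
2	0.134850	0.492260	0.069509	0.303381
3	0.342221	0.036467	0.450580	0.170732
4	0.615929	0.217155	0.147392	0.019524
5	0.291968	0.102561	0.359574	0.245897
6	0.286181	0.097042	0.023943	0.592834
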