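Pos	A	C	G	U
1	0.407047	0.153930	0.181635	0.257388
2	0.004669	0.257342	0.175913	0.562076
3	0.476766	0.020796	0.014140	0.488298
4	0.451848	0.070017	0.003626	0.474509
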