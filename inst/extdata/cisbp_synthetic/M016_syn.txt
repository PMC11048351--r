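Pos	A	C	G	U
1	0.166844	0.609488	0.194656	0.029012
2	0.359291	0.020214	0.169965	0.450530
3	0.700739	0.132659	0.077683	0.088919
4	0.200144	0.003945	0.295799	0.500112
5	0.159787	0.415066	0.009167	0.415980
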