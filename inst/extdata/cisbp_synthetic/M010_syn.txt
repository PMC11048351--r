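Pos	A	C	G	U
1	0.419000	0.384362	0.084403	0.112235
2	0.174769	0.000785	0.536658	0.287788
3	0.049071	0.047096	0.063506	0.840327
4	0.168181	0.004683	0.255946	0.571190
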