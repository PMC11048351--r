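Pos	A	C	G	U
1	0.396697	0.171902	0.171234	0.260167
2	0.259796	0.458243	0.078976	0.202985
3	0.334663	0.011595	0.232245	0.421497
4	0.309170	0.482585	0.192918	0.015327
5	0.553253	0.335685	0.022396	0.088666
6	0.022239	0.352099	0.215592	0.410070
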