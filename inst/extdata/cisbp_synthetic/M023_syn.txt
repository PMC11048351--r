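Pos	A	C	G	U
1	0.323152	0.265216	0.350650	0.060982
2	0.033185	0.184772	0.451606	0.330437
3	0.375374	0.247128	0.216383	0.161115
4	0.050189	0.481244	0.369412	0.099155
5	0.062396	0.435785	0.410313	0.091506
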