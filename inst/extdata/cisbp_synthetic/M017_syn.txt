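Pos	A	C	G	U
1	0.111419	0.345113	0.224967	0.318501
2	0.238049	0.073925	0.430928	0.257098
3	0.038080	0.540879	0.312045	0.108996
4	0.181475	0.130892	0.077567	0.610066
5	0.263605	0.117597	0.481604	0.137194
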