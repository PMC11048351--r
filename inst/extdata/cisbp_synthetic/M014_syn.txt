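Pos	A	C	G	U
1	0.053142	0.104157	0.697955	0.144746
2	0.133273	0.521934	0.129413	0.215380
3	0.577977	0.088237	0.024332	0.309454
4	0.236343	0.620934	0.039091	0.103632
5	0.059444	0.551339	0.155173	0.234044
6	0.526908	0.033330	0.043261	0.396501
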