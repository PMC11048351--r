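Pos	A	C	G	U
1	0.258578	0.421987	0.139365	0.180070
2	0.565303	0.094709	0.295558	0.044430
3	0.209967	0.320703	0.051097	0.418233
4	0.157356	0.117876	0.075057	0.649711
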