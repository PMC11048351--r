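Pos	A	C	G	U
1	0.209717	0.037150	0.080943	0.672190
2	0.062802	0.273906	0.271517	0.391775
3	0.196268	0.124108	0.019637	0.659987
4	0.374516	0.028261	0.184879	0.412344
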