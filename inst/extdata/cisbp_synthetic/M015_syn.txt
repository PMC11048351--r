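Pos	A	C	G	U
1	0.156582	0.628021	0.023451	0.191946
2	0.093783	0.002170	0.272908	0.631139
3	0.055334	0.767415	0.148288	0.028963
4	0.093799	0.458529	0.369005	0.078667
5	0.101785	0.002851	0.038084	0.857280
6	0.074072	0.071832	0.508154	0.345942
7	0.447772	0.394960	0.110051	0.047217
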