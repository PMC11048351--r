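Pos	A	C	G	U
1	0.349192	0.304619	0.098159	0.248030
2	0.119988	0.336916	0.343434	0.199662
3	0.275433	0.021768	0.430753	0.272046
4	0.361822	0.204723	0.363395	0.070060
5	0.610622	0.127758	0.233294	0.028326
6	0.028831	0.531940	0.323170	0.116059
7	0.357122	0.287152	0.194553	0.161173
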