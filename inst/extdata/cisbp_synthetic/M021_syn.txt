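Pos	A	C	G	U
1	0.027646	0.896251	0.002570	0.073533
2	0.279150	0.222768	0.335621	0.162461
3	0.044344	0.408081	0.186310	0.361265
4	0.056635	0.080372	0.030468	0.832525
5	0.190195	0.473132	0.008495	0.328178
6	0.528748	0.095354	0.182016	0.193882
7	0.168509	0.365760	0.041036	0.424695
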