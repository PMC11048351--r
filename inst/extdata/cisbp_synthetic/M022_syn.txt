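Pos	A	C	G	U
1	0.218332	0.175493	0.571645	0.034530
2	0.072901	0.008455	0.127584	0.791060
3	0.038247	0.267612	0.141494	0.552647
4	0.131793	0.391739	0.240826	0.235642
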