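domain	start	end
A1	1	372
A2	373	740
B	741	1647
A3	1648	2019
C1	2020	2172
C2	2173	2332
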