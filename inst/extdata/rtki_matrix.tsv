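alternative	GF1	GF2	GF3
In1	0.333	0.250	0.333
In2	0.333	0.250	0.333
In3	1.000	0.000	0.333
In4	1.000	0.666	0.666
In5	0.333	0.000	0.333
In6	1.000	0.333	0.666
In7	0.666	0.000	0.333
In8	1.000	0.250	0.333
In9	1.000	1.000	0.333
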