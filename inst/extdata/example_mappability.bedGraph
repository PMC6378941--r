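sim1	9999	15000	1
sim1	15000	20000	0.8
sim1	20000	24000	0.5
sim1	24000	40000	1
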