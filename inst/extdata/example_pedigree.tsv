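family_id	offspring_id	father_id	mother_id
F001	F001_o	F001_f	F001_m
F002	F002_o	F002_f	F002_m
F003	F003_o	F003_f	F003_m
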