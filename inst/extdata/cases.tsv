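case_id	diagnosis_id	phenotype_ids
p1	BDO:1000001	HP:0000772,HP:0008921
p2	BDO:1000001	HP:0000774,HP:0008921
p3	BDO:1000001	HP:0000772,HP:0008905
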