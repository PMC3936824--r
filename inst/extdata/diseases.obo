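format-version: 1.2

[Term]
id: BDO:0000000
name: Bone dysplasia

[Term]
id: BDO:0000001
name: FGFR3 group
is_a: BDO:0000000 ! Bone dysplasia

[Term]
id: BDO:1000001
name: Achondroplasia
is_a: BDO:0000001 ! FGFR3 group

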