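format-version: 1.2

[Term]
id: HP:0000001
name: All

[Term]
id: HP:0000256
name: Macrocephaly
is_a: HP:0000929 ! Abnormality of the skull

[Term]
id: HP:0000765
name: Abnormality of the thorax
is_a: HP:0000001 ! All

[Term]
id: HP:0000772
name: Abnormality of the ribs
is_a: HP:0000765 ! Abnormality of the thorax

[Term]
id: HP:0000774
name: Narrow chest
is_a: HP:0005257 ! Thoracic hypoplasia

[Term]
id: HP:0000929
name: Abnormality of the skull
is_a: HP:0000001 ! All

[Term]
id: HP:0004481
name: Progressive macrocephaly
is_a: HP:0000256 ! Macrocephaly

[Term]
id: HP:0004482
name: Relative macrocephaly
is_a: HP:0000256 ! Macrocephaly

[Term]
id: HP:0004488
name: Macrocephaly at birth
is_a: HP:0000256 ! Macrocephaly

[Term]
id: HP:0005257
name: Thoracic hypoplasia
is_a: HP:0000765 ! Abnormality of the thorax

[Term]
id: HP:0008873
name: Disproportionate short-limb short stature
is_a: HP:0000001 ! All

[Term]
id: HP:0008905
name: Rhizomelic short stature
is_a: HP:0008873 ! Disproportionate short-limb short stature

[Term]
id: HP:0008921
name: Neonatal short-limb short stature
is_a: HP:0008873 ! Disproportionate short-limb short stature

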