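name: fsg_default
rules:
- id: R1
  advise: refer_expert
  when:
  - field: imaging_pattern
    op: eq
    value: heterogeneous_suspicious
- id: R2a
  advise: refer_expert
  when:
  - field: imaging_performed
    op: eq
    value: yes
  - field: size
    op: ge
    value: 50.0
- id: R2b
  advise: refer_expert
  when:
  - field: imaging_performed
    op: eq
    value: yes
  - field: depth
    op: eq
    value: deep_or_mixed
- id: R3a
  advise: complementary_imaging
  when:
  - field: imaging_performed
    op: eq
    value: no
  - field: size
    op: ge
    value: 50.0
- id: R3b
  advise: complementary_imaging
  when:
  - field: imaging_performed
    op: eq
    value: no
  - field: depth
    op: eq
    value: deep_or_mixed
- id: R3c
  advise: complementary_imaging
  when:
  - field: imaging_performed
    op: eq
    value: no
  - field: signs
    op: any_sign
    value:
    - growth
    - pain
    - hardness
- id: R4
  advise: local_management
  when:
  - field: imaging_performed
    op: eq
    value: yes
  - field: imaging_pattern
    op: eq
    value: lipomatous_homogeneous
  - field: depth
    op: eq
    value: superficial
  - field: size
    op: lt
    value: 50.0
  - field: signs
    op: no_signs
- id: R5
  advise: local_management
  when:
  - field: imaging_performed
    op: eq
    value: yes
  - field: imaging_pattern
    op: eq
    value: homogeneous_other
  - field: depth
    op: eq
    value: superficial
  - field: size
    op: lt
    value: 30.0
  - field: signs
    op: no_signs
- id: R6
  advise: complementary_imaging
  when:
  - field: imaging_performed
    op: eq
    value: no
default: refer_expert
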