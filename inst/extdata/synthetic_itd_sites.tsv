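patient	insertion_aa
P1	598
P2	613
P3	601
P3	615
P4	598
P5	621
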