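p1: 0.05
p2:
- 0.90000000000000002
- 0.0
- 0.0
p3:
- 30.0
- 1.0
- 1.0
p4:
- 0.02
- 0.01
- 0.01
p5:
- 1.0
- 1.0
- 1.0
mode: microplate
m_const: 0.001
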