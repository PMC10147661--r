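sgrna:
- id: sg1
  b: 0.02
  k_sg: 0.29999999999999999
  kf_dsd: 0.0125
- id: sg1t4
  b: 0.02
  k_sg: 0.29999999999999999
  kf_dsd: 0.002
- id: sg2
  b: 0.02
  k_sg: 0.29999999999999999
  kf_dsd: 0.00833333333333333
- id: sg3
  b: 0.02
  k_sg: 0.29999999999999999
  kf_dsd: 0.005
- id: sg4
  b: 0.02
  k_sg: 0.29999999999999999
  kf_dsd: 0.01
- id: sg4t4
  b: 0.02
  k_sg: 0.29999999999999999
  kf_dsd: 0.00166666666666667
shared:
  kr_dsd: 0.01
  kf_ds: 0.02
  kr_ds: 0.20000000000000001
  n_hill: 1.5
  K_m: 0.01
  k2: 0.25
d_rna:
  '1': 0.25
  '2': 0.23000000000000001
  '3': 0.20999999999999999
  '4': 0.20000000000000001
  '5': 0.19
  '6': 0.17999999999999999
dcas_total:
  '1': 150.0
  '2': 180.0
  '3': 210.0
  '4': 240.0
  '5': 270.0
  '6': 300.0
nodes:
- node: A
  reporter: mKO2
  dna_total: 30.0
  b: 0.02
  k_mrna: .na.real
  k_pi: 2.0
  m_pi: 0.023
  d_pi: 0.025
- node: B
  reporter: mKate2
  dna_total: 30.0
  b: 0.0
  k_mrna: 0.59999999999999998
  k_pi: 2.0
  m_pi: 0.035
  d_pi: 0.025
- node: C
  reporter: sfGFP
  dna_total: 30.0
  b: 0.0
  k_mrna: 0.59999999999999998
  k_pi: 2.0
  m_pi: 0.10000000000000001
  d_pi: 0.025
ara_translation:
  base: 0.20000000000000001
  h: 2.0
  K_t: 0.01
scaling:
  mKO2: 20.0
  mKate2: 10.0
  sfGFP: 50.0
od_cells: 800000000.0
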