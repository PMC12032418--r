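air:
  name: Air
  c0: 343.0
  rho: 1.2
  alpha_ref_1MHz: 0.0
  power_b: 1.0
abdominal_tissue:
  name: Abdominal tissue
  c0: 1489.0
  rho: 950.0
  alpha_ref_1MHz: 0.1
  power_b: 1.0
spine_bone:
  name: Spine bone
  c0: 4020.0
  rho: 2700.0
  alpha_ref_1MHz: 0.2
  power_b: 1.0
uterine_tissue:
  name: Uterine tissue
  c0: 1500.0
  rho: 1000.0
  alpha_ref_1MHz: 585.3
  power_b: 1.0
amniotic_fluid:
  name: Amniotic fluid
  c0: 1500.0
  rho: 1000.0
  alpha_ref_1MHz: 0.015
  power_b: 2.0
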