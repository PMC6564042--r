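species:
- id: glc
  role: metabolite
  carbon: 6
- id: ac
  role: metabolite
  carbon: 2
- id: o2
  role: metabolite
  carbon: 0
- id: co2
  role: metabolite
  carbon: 1
- id: atp
  role: metabolite
  carbon: 0
- id: biomass
  role: sink
  carbon: 0
- id: E_res
  role: enzyme
  carbon: 0
- id: E_fer
  role: enzyme
  carbon: 0
- id: E_bms
  role: enzyme
  carbon: 0
reactions:
- id: EX_glc
  stoichiometry:
    glc: 1.0
  k_eff: ~
  enzyme: ~
  lb: 0.0
  ub: '.inf'
  tag: core
- id: RES
  stoichiometry:
    glc: -1.0
    o2: -6.0
    co2: 6.0
    atp: 26.0
  k_eff: 4.7
  enzyme: E_res
  lb: 0.0
  ub: '.inf'
  tag: core
- id: FER
  stoichiometry:
    glc: -1.0
    ac: 2.0
    co2: 2.0
    atp: 12.0
  k_eff: 21.199999999999999
  enzyme: E_fer
  lb: 0.0
  ub: '.inf'
  tag: core
- id: BMS
  stoichiometry:
    glc: -6.7
    atp: -35.0
    biomass: 1.0
  k_eff: 6.0
  enzyme: E_bms
  lb: 0.0
  ub: '.inf'
  tag: core
- id: EX_ac
  stoichiometry:
    ac: -1.0
  k_eff: ~
  enzyme: ~
  lb: 0.0
  ub: '.inf'
  tag: core
- id: EX_o2
  stoichiometry:
    o2: 1.0
  k_eff: ~
  enzyme: ~
  lb: 0.0
  ub: '.inf'
  tag: core
- id: EX_co2
  stoichiometry:
    co2: -1.0
  k_eff: ~
  enzyme: ~
  lb: 0.0
  ub: '.inf'
  tag: core
- id: NGAM
  stoichiometry:
    atp: -1.0
  k_eff: ~
  enzyme: ~
  lb: 1.0
  ub: 1.0
  tag: core
globals:
  UPF: 0.36
  GAM: 35.0
  NGAM: 1.0
  P_total: 0.55
  M_glc: 0.180156
  a_res: 26.0
  a_fer: 12.0
  n_ac: 2.0
  o2_per_glc: 6.0
  c_bms: 6.7
  atp_per_leak: 0.25
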