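physiology:
  Q0: 0.9
  V_mus0: 5.0
  blood_frac: 0.2
  alpha_Q: 0.02
  alpha_V: 0.0004
  tau_QV: 0.4
  V_R: 2.0
  V_W: 2.0
  mito_R: 0.12
  mito_W: 0.08
recruitment:
  W_max: 250.0
  theta: 0.24
  cap_I: 125.0
  cap_II: 125.0
fatigue:
  enabled: no
  decline: 0.05
rest:
  blood:
    O2: 6.0
    CO2: 1.2
    Glc: 4.2
    Lac: 1.0
    Pyr: 0.08
    Ala: 0.45
    Glr: 0.06
    FFA: 0.7
    H: 3.981072e-05
  cyt:
    I:
      ATP: 6.2
      PCr: 20.0
      Cr: 13.0
      Pi: 2.9
      Gly: 80.0
      Glc: 0.5
      Pyr: 0.1
      Lac: 1.1
      Ala: 0.6
      Glr: 0.08
      FFA: 0.3
      FAC: 0.01
      CoA: 0.02
      O2: 4.0
      CO2: 1.5
      H: 8.912509e-05
    II:
      ATP: 6.2
      PCr: 23.0
      Cr: 11.0
      Pi: 2.9
      Gly: 90.0
      Glc: 0.5
      Pyr: 0.1
      Lac: 1.1
      Ala: 0.6
      Glr: 0.08
      FFA: 0.3
      FAC: 0.01
      CoA: 0.02
      O2: 4.0
      CO2: 1.5
      H: 8.912509e-05
  mit:
    Pyr: 0.06
    O2: 3.9
    CO2: 1.6
    NADH: 0.3
    FAC: 0.005
    CoA: 0.025
    Pi: 2.9
    H: 8.912509e-05
metabolism:
  atpase0:
    I: 0.3
    II: 0.25
  fat_share:
    I: 0.6
    II: 0.4
  lac_rel0: 0.012
  ala_rel0: 0.001
  pyr_rel0: 0.0005
  gp0: 0.002
  lipolysis0: 0.0002
  P_per_NADH: 2.5
  nadh_per_pyr: 5.0
  co2_per_pyr: 3.0
  nadh_per_fac: 46.0
  co2_per_fac: 16.0
  atp_cost_gs: 2.0
  atp_cost_fac: 2.0
  h_per_atpase: 0.3
  h_per_lac: 1.0
  n_ADP_ox: 3.0
  NAD_tot: 3.0
  buffer_beta: 22.0
  Keq_CK: 1.66e+09
  Keq_AK: 1.05
  k_CK: 5.0
  k_AK: 10.0
  k_LDH: 20.0
  k_ALT: 2.0
  Km:
    ATP_atpase: 0.5
    Gly_gp: 20.0
    Glc_gly: 0.3
    Pi_gly: 1.5
    ADP_gly: 0.3
    K_gly_gs: 150.0
    Pyr_pdh: 0.08
    NAD_pdh: 1.0
    FAC_box: 0.004
    NADH_ox: 0.15
    O2_ox: 0.5
    ADP_ox: 0.8
    Pi_ox: 2.0
    FFA_fac: 0.2
    CoA_fac: 0.01
  alpha:
    atpase:
      I: 0.3
      II: 0.36
    glycolysis:
      I: 0.5
      II: 1.2
    gp:
      I: 1.6
      II: 3.2
    gs:
      I: 0.02
      II: 0.02
    pdh:
      I: 0.5
      II: 0.45
    fat:
      I: 0.24
      II: 0.3
    ox:
      I: 0.035
      II: 0.032
    lipolysis:
      I: 0.02
      II: 0.02
  tau:
    atpase: 0.18
    glycolysis: 0.25
    gp: 0.25
    gs: 1.0
    pdh: 0.25
    fat: 1.0
    ox: 0.3
    lipolysis: 2.0
transport:
  KM_bl:
    Glc: 1.5
    Pyr: 0.15
    Lac: 2.0
    FFA: 0.3
    H: 0.0001
  alpha_bl:
    O2: 0.15
    CO2: 0.3
    Glc: 0.06
    Lac: 0.06
    Pyr: 0.05
    Ala: 0.02
    Glr: 0.02
    FFA: 0.4
    H: 0.15
  KM_mt:
    Pyr: 0.1
    FAC: 0.01
    CoA: 0.02
    Pi: 2.0
    H: 0.0001
  alpha_mt:
    O2: 0.05
    CO2: 0.15
    Pyr: 0.45
    FAC: 0.25
    CoA: 0.25
    Pi: 0.05
    H: 0.05
  Rmax_Pi_mt: 0.5
  Rmax_H_mt: 0.2
  Rmax_H_bl: 0.6
  sigma_H_blood: 250000.0
  beta_blood: 25.0
  tau: 0.4
signaling:
  Ca_rest: 0.1
  Ca_slope: 1.5
  tau_Ca: 0.5
  K_CaM: 1.0
  n_CaM: 4.0
  camkii:
    k_basal: 0.01
    k_cam: 0.6
    k_dp: 0.3
  calcineurin:
    K: 0.3
  camkk2:
    K: 0.5
  crtc:
    k_basal: 0.005
    k_cn: 0.5
    k_rp: 0.13
  lkb1: 1.0
  ampk:
    total:
      a2b2g1: 0.65
      a2b2g3: 0.2
      a1b2g1: 0.15
    a2b2g3:
      k_ph: 0.02
      c_camkk: 64.0
      k_dp: 1.9
      K_amp: 0.002
      ATP0: 6.2
      baseline: 0.2
      c_act: 1.0
      K_allo: 3.0
      ratio0: 2.0e-05
    a2b2g1:
      k_ph: 0.01
      c_camkk: 0.15
      k_dp: 0.28
      K_amp: 0.1
      ATP0: 6.2
      baseline: 1.0
      c_act: 1.0
      K_allo: 3.0
      ratio0: 2.0e-05
    a1b2g1:
      k_ph: 0.01
      c_camkk: 0.15
      k_dp: 0.33
      K_amp: 0.1
      ATP0: 6.2
      baseline: 1.0
      c_act: 1.0
      K_allo: 3.0
      ratio0: 2.0e-05
  creb:
    k_basal: 0.01
    k_camkii: 0.5
    k_ampk: 0.05
    k_dp: 0.25
genes:
  K_drive: 30.0
  n_drive: 1.0
  NR4A3:
    k_deg: 0.05
    fold_max: 14.0
  NR4A2:
    k_deg: 0.023
    fold_max: 9.0
  X:
    k_deg: 0.025
    fold_max: 6.0
    k_trans: 0.1
    k_deg_prot: 0.008
  PPARGC1A:
    k_deg: 0.006
    fold_max: 8.0
    K_X: 8.0
  direct_creb_regulation: no
  x_factor_enabled: yes
solver:
  rtol: 1.0e-08
  atol: 1.0e-10
  dt_out: 0.1
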