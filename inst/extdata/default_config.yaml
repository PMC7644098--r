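# craswitch reference configuration
# Units: time h, mass g, extracellular concentrations mM, intracellular
# concentrations mmol per g dry weight; K_CraA_DNA in molecules per g
# (active-Cra amount divided by cell mass). dt and log cadence in minutes.
# The kinetics block is the calibrated default parameter set (version 0.1.0).
kinetics:
  B0: 3.0e-13
  c: 0.0896
  e_ref: 100.0
  V_Gi: 10.0
  K_Gi: 1.5
  V_Ai: 36.0
  K_Ai: 0.8
  V_Lg: 12.0
  K_Lg: 0.5
  V_An: 1773.0
  K_fbp_An: 3.0
  K_pep_An: 0.035
  n_An: 2.0
  m_pep_An: 3.0
  L_An: 5000.0
  K_Cra_fbp: 0.1
  n_Cra: 2.0
  K_CraA_DNA: 6.5e+14
  alpha_Ai_on: 20.0
  alpha_Ai_off: 0.0
expression:
  eta2_constitutive: 0.2
  mean_copies: 100.0
  gamma_p_ai: 0.0
environment:
  substrate_start: glucose
  S_in_glucose: 10.0
  S_in_acetate: 20.0
  D: 0.08
  kappa: 3.4e+08
schedule:
  mode: single_switch
  switch_time: 48.0
  period: 48.0
  random_mean: 48.0
  t_end: 96.0
  stop_on_fixation: no
population:
  groups:
  - n0: 2000.0
    K_cra_fbp: 0.1
    eta2_cra: 0.2
    label: group1
logging:
  log_every_min: 1.0
seed: 1
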