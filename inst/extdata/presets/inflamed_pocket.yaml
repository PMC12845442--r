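# Generic pocket formulation in an inflamed (high GCF flow) pocket.
# Differs from healthy_pocket only in Q_GCF.
name: inflamed_pocket
note: >
  Generic Weibull-release pocket formulation; inflamed GCF flow
  (0.3 uL/min, mid 0.2-0.5 range). Pairs with healthy_pocket.
physiology:
  V_S: 0.8          # mL
  Q_S: 0.4          # mL/min
  R_in: 0.0         # ug/min
  A_SM: 4.0         # cm2
  A_SB: 2.0         # cm2 (assumption)
  A_SP: 0.05        # cm2 (assumption)
  A_BP: 0.1         # cm2 (assumption)
  Gamma_max: 10.0   # ug/cm2
  k_ads: 0.5        # mL/cm2/min
  k_des: 0.05       # 1/min
  P_SM: 5.0e-5      # cm/min
  K_p_T: 5.0        # dimensionless
  V_T: 0.075        # mL
  CL_local: 0.05    # mL/min
  D_eff: 3.0e-7     # cm2/s
  k_bind: 5.0e-5    # 1/s (assumption)
  L_B: 0.02         # cm
  V_P: 1.0          # uL
  Q_GCF: 0.3        # uL/min (inflamed 0.2-0.5)
formulation:
  family: weibull
  coefficients:
    a: 2.0e-3       # min^-b
    b: 0.9
  dose: 500.0       # ug
dosing:
  - route: pocket_formulation
    amount: 500.0
    start: 0.0
simulation:
  t_end: 4320.0     # 3 days
  dt_out: 20.0
  N_x: 40
  mode: coupled
pkpd:
  MIC: 1.0          # ug/mL, placeholder
  interval: [0.0, 4320.0]
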