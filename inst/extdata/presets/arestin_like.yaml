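# Minocycline PLGA-microsphere scenario: mixed diffusion/degradation
# release (Peppas-Sahlin), healthy-pocket GCF flow by default; the
# inflamed variant raises Q_GCF to 0.3 uL/min. Illustrative.
name: arestin_like
note: >
  Peppas-Sahlin microsphere release; coefficients chosen so release
  completes in roughly 8 days. Pairs with an inflamed variant (Q_GCF
  0.3 uL/min) to show inflammation-accelerated wash-out.
physiology:
  V_S: 0.8          # mL
  Q_S: 0.4          # mL/min
  R_in: 0.0         # ug/min
  A_SM: 4.0         # cm2
  A_SB: 2.0         # cm2 (assumption)
  A_SP: 0.05        # cm2 (assumption)
  A_BP: 0.1         # cm2 (assumption)
  Gamma_max: 10.0   # ug/cm2
  k_ads: 0.3        # mL/cm2/min (minocycline binds less avidly than CHX)
  k_des: 0.05       # 1/min
  P_SM: 5.0e-5      # cm/min
  K_p_T: 5.0        # dimensionless
  V_T: 0.075        # mL
  CL_local: 0.05    # mL/min
  D_eff: 3.0e-7     # cm2/s
  k_bind: 5.0e-5    # 1/s (assumption)
  L_B: 0.02         # cm
  V_P: 1.0          # uL
  Q_GCF: 0.075      # uL/min (healthy 0.05-0.1; inflamed variant: 0.3)
formulation:
  family: peppas_sahlin
  coefficients:
    k1: 0.0096      # min^-m, Fickian term
    k2: 7.3e-5      # min^-2m, relaxational term
    m: 0.45
  dose: 1000.0      # ug minocycline
dosing:
  - route: pocket_formulation
    amount: 1000.0
    start: 0.0
simulation:
  t_end: 11520.0    # 8 days
  dt_out: 60.0
  N_x: 40
  mode: coupled
pkpd:
  MIC: 1.0          # ug/mL, placeholder
  interval: [0.0, 11520.0]
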