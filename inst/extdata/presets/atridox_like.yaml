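# Doxycycline in situ gel scenario: direct pocket deposition with
# near-first-order release over about seven days and minimal saliva
# coupling (small saliva-biofilm interface). Illustrative.
name: atridox_like
note: >
  Direct-to-pocket gel; salivary dilution plays little role, so the
  saliva-biofilm interface is kept small and clearance is dominated by
  GCF flow and biofilm uptake.
physiology:
  V_S: 0.8          # mL
  Q_S: 0.4          # mL/min
  R_in: 0.0         # ug/min
  A_SM: 4.0         # cm2
  A_SB: 0.5         # cm2 (small: gel largely bypasses saliva)
  A_SP: 0.0         # cm2 (pocket sealed from saliva)
  A_BP: 0.1         # cm2 (assumption)
  Gamma_max: 10.0   # ug/cm2
  k_ads: 0.3        # mL/cm2/min
  k_des: 0.05       # 1/min
  P_SM: 5.0e-5      # cm/min
  K_p_T: 5.0        # dimensionless
  V_T: 0.075        # mL
  CL_local: 0.05    # mL/min
  D_eff: 3.0e-7     # cm2/s
  k_bind: 5.0e-5    # 1/s (assumption)
  L_B: 0.02         # cm
  V_P: 1.0          # uL
  Q_GCF: 0.3        # uL/min (treated pockets are typically inflamed)
formulation:
  family: weibull
  coefficients:
    a: 2.3e-4       # min^-b; ~90% released by day 7
    b: 1.0
  dose: 5000.0      # ug doxycycline (illustrative per-pocket amount)
dosing:
  - route: pocket_formulation
    amount: 5000.0
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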