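# Chlorhexidine chip scenario: biphasic release (24 h first-order burst,
# then quasi-zero-order until ~8.5 days), strong pellicle affinity,
# inflamed-pocket GCF flow. Illustrative, not a label claim.
name: periochip_like
note: >
  Biphasic chip release into an inflamed pocket with active pellicle
  binding. Interface areas (A_SB, A_SP, A_BP), the biofilm binding rate
  and the MIC are assumptions: the literature supplies ranges and
  qualitative profiles only.
physiology:
  V_S: 0.8          # mL (typical 0.7-1.0)
  Q_S: 0.4          # mL/min (resting 0.3-0.5)
  R_in: 0.0         # ug/min
  A_SM: 4.0         # cm2 (typical 2-6)
  A_SB: 2.0         # cm2 (assumption)
  A_SP: 0.05        # cm2 (assumption)
  A_BP: 0.1         # cm2 (assumption)
  Gamma_max: 10.0   # ug/cm2 (typical 5-15)
  k_ads: 0.5        # mL/cm2/min (typical 0.1-1.2)
  k_des: 0.05       # 1/min (typical 0.01-0.1)
  P_SM: 5.0e-5      # cm/min (typical 1e-5 - 1e-4)
  K_p_T: 5.0        # dimensionless (typical 2-10)
  V_T: 0.075        # mL (typical 0.05-0.1)
  CL_local: 0.05    # mL/min (typical 0.01-0.1)
  D_eff: 3.0e-7     # cm2/s (typical 1e-7 - 5e-7)
  k_bind: 5.0e-5    # 1/s (assumption)
  L_B: 0.02         # cm (typical 0.01-0.03, i.e. 100-300 um)
  V_P: 1.0          # uL (typical 0.5-2)
  Q_GCF: 0.3        # uL/min (inflamed 0.2-0.5)
formulation:
  family: biphasic_burst_zero_order
  coefficients:
    burst_fraction: 0.4
    burst_rate: 0.003      # 1/min; ~98% of the burst inside 24 h
    t_end: 12240.0         # min = 8.5 days (7-10 day zero-order phase)
  dose: 2500.0             # ug chlorhexidine
dosing:
  - route: pocket_formulation
    amount: 2500.0
    start: 0.0
simulation:
  t_end: 12960.0           # 9 days: release window plus wash-out tail
  dt_out: 60.0
  N_x: 40
  mode: coupled
pkpd:
  MIC: 1.0                 # ug/mL, placeholder (no numeric MIC published)
  interval: [0.0, 12960.0]
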