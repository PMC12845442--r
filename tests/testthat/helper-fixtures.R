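# Shared fixtures: small physiologies and grids used across test files.

# All transport pathways off except salivary dilution.
dilution_only_physiology <- function(C_extra = list()) {
  do.call(oral_physiology, c(list(
    V_S = 0.8, Q_S = 0.4, A_SM = 2, A_SB = 0, A_SP = 0,
    k_ads = 0, k_des = 0.05, P_SM = 0, P_SP = 0), C_extra))
}

# Pocket decays only through GCF wash-out.
pocket_only_physiology <- function(Q_GCF = 0.3) {
  oral_physiology(A_SB = 0, A_SP = 0, k_ads = 0, P_SM = 0, P_SP = 0,
                  Q_GCF = Q_GCF)
}

coarse_grid <- function(t_end, N_x = 20, ...) {
  simulation_grid(t_end = t_end, dt_out = t_end / 100, N_x = N_x, ...)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}
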