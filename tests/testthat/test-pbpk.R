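canonical_default <- function(...) to_canonical(oral_physiology(...))

test_that("saliva-mucosa flux follows the partition-referenced form", {
  p <- canonical_default(P_SM = 1e-4, K_p_T = 5)
  expect_equal(flux_saliva_mucosa(10, 0, p), 1e-3)
  expect_equal(flux_saliva_mucosa(10, 50, p), 0)   # C_T = K_p * C_S
  # antisymmetry in the driving-force difference
  expect_equal(flux_saliva_mucosa(4, 10, p), -flux_saliva_mucosa(0, 10, p))
})

test_that("pellicle kinetics: Langmuir ceiling, washout limb and equilibrium", {
  p <- canonical_default(Gamma_max = 10, k_ads = 0.5, k_des = 0.05)
  expect_equal(rhs_pellicle(5, 10, p), -0.05 * 10)   # saturated: pure desorption
  expect_equal(rhs_pellicle(0, 4, p), -0.05 * 4)     # washout limb
  # long-run equilibrium at fixed C_S matches the Langmuir isotherm
  C_S <- 2
  sol <- deSolve::ode(y = c(G = 0), times = c(0, 1000),
                      func = function(t, y, parms)
                        list(rhs_pellicle(C_S, y[1], p)),
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  G_eq <- p$Gamma_max * p$k_ads * C_S / (p$k_ads * C_S + p$k_des)
  expect_equal(unname(sol[2, 2]), G_eq, tolerance = 1e-6)
})

test_that("tissue balance reaches its closed-form steady state under fixed C_S", {
  p <- canonical_default()
  C_S <- 8
  sol <- deSolve::ode(y = c(C_T = 0), times = c(0, 5000),
                      func = function(t, y, parms)
                        list(rhs_tissue(C_S, y[1], p)),
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  ss <- p$P_SM * p$A_SM * C_S / (p$P_SM * p$A_SM / p$K_p_T + p$CL_local)
  expect_rel_equal(unname(sol[2, 2]), ss, 1e-6)
  expect_equal(rhs_tissue(0, 0, p), 0)
})

test_that("salivary dilution alone follows exp(-Q_S t / V_S)", {
  p <- dilution_only_physiology()
  g <- simulation_grid(t_end = 1, dt_out = 0.1, N_x = 10)
  s <- simulate_oral(p, dose_event(1600, "saliva_bolus"), grid = g)
  expect_equal(s$C_S[1], 2000)
  # ~40% reduction in the first minute at resting flow
  expect_rel_equal(s$C_S[length(s$C_S)] / s$C_S[1], exp(-0.5), 1e-6)
})

test_that("steady salivary infusion reaches C_ss = R_in / Q_S", {
  p <- dilution_only_physiology(list(R_in = 40))
  g <- simulation_grid(t_end = 50, dt_out = 1, N_x = 10)
  s <- simulate_oral(p, list(), grid = g)
  expect_rel_equal(s$C_S[length(s$C_S)], 40 / 0.4, 1e-3)
})

test_that("empty system stays identically zero", {
  p <- oral_physiology()
  g <- coarse_grid(30)
  s <- simulate_oral(p, list(), grid = g)
  expect_true(all(s$C_S == 0 & s$C_T == 0 & s$C_P == 0 & s$Gamma == 0))
  expect_true(all(s$C_B == 0))
})

test_that("pocket wash-out half-life matches V_P ln2 / Q_GCF within 1%", {
  p <- pocket_only_physiology(Q_GCF = 0.3)
  g <- simulation_grid(t_end = 10, dt_out = 0.05, N_x = 10)
  s <- simulate_oral(p, list(), grid = g, init = list(C_P = 100))
  t_half <- stats::approx(s$C_P, s$times, xout = 50)$y
  expect_rel_equal(t_half, 0.001 * log(2) / 3e-4, 0.01)  # 2.31 min
})

test_that("pocket steady state under constant release is (J A + R)/Q_GCF", {
  # direct-release-only pocket: constant zero-order source
  p <- pocket_only_physiology(Q_GCF = 0.3)
  rel <- release_model("biphasic_burst_zero_order",
                       c(burst_fraction = 0, burst_rate = 1e-6,
                         zero_order_rate = 1e-3, t_end = 1000), M_inf = 1)
  # R_release = M_inf * 1e-3 ug/min, constant until t_end
  g <- simulation_grid(t_end = 400, dt_out = 5, N_x = 10)
  s <- simulate_oral(p, dose_event(200, "pocket_formulation"), rel, g,
                     mode = "sealed")
  R <- 200 * 1e-3
  expect_rel_equal(s$C_P[length(s$C_P)], R / 3e-4, 1e-3)
})

test_that("uniform biofilm profile with k_bind = 0 has zero derivatives", {
  p <- canonical_default(k_bind = 0)
  out <- biofilm_derivatives(rep(7, 30), C_S = 7, C_P = 0, p, mode = "sealed")
  expect_equal(out$dC_B, rep(0, 30))
  expect_equal(out$J_SB, 0)
})

test_that("early-time biofilm penetration matches the erfc analytic solution", {
  p <- oral_physiology(k_bind = 0, D_eff = 3e-7, L_B = 0.02)
  g <- simulation_grid(t_end = 1, dt_out = 0.5, N_x = 200)
  sl <- simulate_biofilm_slab(p, C0 = 100, g)
  D <- 3e-7 * 60
  i <- nrow(sl$C_B)
  analytic <- 100 * 2 * stats::pnorm(-sl$x / sqrt(2 * D * 1))  # erfc(x/(2 sqrt(D t)))
  # max nodewise deviation relative to the surface concentration
  expect_lt(max(abs(sl$C_B[i, ] - analytic)) / 100, 0.01)
})

test_that("mid-film penetration time has the magnitude of L^2/D_eff", {
  p <- oral_physiology(k_bind = 0, D_eff = 3e-7, L_B = 0.02)
  g <- simulation_grid(t_end = 60, dt_out = 0.25, N_x = 100)
  sl <- simulate_biofilm_slab(p, C0 = 100, g)
  mid <- sl$C_B[, which.min(abs(sl$x - 0.01))]
  t50 <- stats::approx(mid, sl$times, xout = 50)$y
  tau <- 0.02^2 / (3e-7 * 60)   # ~22 min
  expect_gt(t50, tau / 10)
  expect_lt(t50, tau * 10)
})

test_that("closed system conserves mass to 1e-6 over 1000 minutes", {
  p <- oral_physiology(Q_S = 0, Q_GCF = 0, CL_local = 0, k_bind = 0,
                       R_in = 0)
  g <- simulation_grid(t_end = 1000, dt_out = 10, N_x = 40)
  s <- simulate_oral(p, dose_event(500, "saliva_bolus"), grid = g,
                     mode = "sealed")
  mb <- mass_balance(s)
  expect_lt(max(abs(mb$relative_error)), 1e-6)
  # and drug actually moved into pellicle, tissue and biofilm
  expect_gt(s$Gamma[length(s$Gamma)], 0)
  expect_gt(max(s$C_B), 0)
})

test_that("open system ledgers close the balance for mixed dosing", {
  p <- oral_physiology()
  rel <- release_model("weibull", c(a = 2e-3, b = 0.9))
  doses <- list(dose_event(300, "saliva_bolus", start = 0),
                dose_event(200, "saliva_bolus", start = 45),
                dose_event(600, "saliva_infusion", start = 10, duration = 60),
                dose_event(400, "pocket_formulation", start = 20))
  g <- simulation_grid(t_end = 240, dt_out = 2, N_x = 30)
  s <- simulate_oral(p, doses, rel, g)
  mb <- mass_balance(s)
  expect_lt(max(abs(mb$relative_error)), 1e-6)
  # the infusion ledger ends at the administered amount
  expect_rel_equal(s$ledgers$infused[length(s$times)], 600, 1e-6)
})

test_that("doubling the dose doubles every concentration (linear kinetics)", {
  p <- oral_physiology(k_ads = 0)   # Langmuir binding is the only nonlinearity
  rel <- release_model("weibull", c(a = 2e-3, b = 0.9))
  g <- simulation_grid(t_end = 200, dt_out = 2, N_x = 40,
                       rtol = 1e-11, atol = 1e-13)
  s1 <- simulate_oral(p, dose_event(500, "pocket_formulation"), rel, g)
  s2 <- simulate_oral(p, dose_event(1000, "pocket_formulation"), rel, g)
  for (comp in c("C_S", "C_T", "C_P")) {
    dev <- max(abs(s2[[comp]] - 2 * s1[[comp]])) / max(2 * s1[[comp]], 1e-300)
    expect_lt(dev, 1e-8, label = comp)
  }
})

test_that("pocket AUC decreases monotonically with GCF flow", {
  rel <- release_model("weibull", c(a = 2e-3, b = 0.9))
  g <- simulation_grid(t_end = 400, dt_out = 5, N_x = 30)
  aucs <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.5), function(q) {
    p <- oral_physiology(Q_GCF = q)
    s <- simulate_oral(p, dose_event(500, "pocket_formulation"), rel, g)
    auc(profile_from_simulation(s, "pocket"))
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
})

test_that("pocket AUC converges under biofilm grid refinement", {
  rel <- release_model("weibull", c(a = 2e-3, b = 0.9))
  run <- function(N) {
    g <- simulation_grid(t_end = 120, dt_out = 2, N_x = N)
    s <- simulate_oral(oral_physiology(), dose_event(500, "pocket_formulation"),
                       rel, g, mode = "coupled")
    auc(profile_from_simulation(s, "pocket"))
  }
  a200 <- run(200); a400 <- run(400)
  expect_lt(abs(a400 - a200) / a200, 0.005)
})

test_that("boluses given mid-run create jumps and keep the balance closed", {
  p <- dilution_only_physiology()
  g <- simulation_grid(t_end = 60, dt_out = 0.5, N_x = 10)
  s <- simulate_oral(p, list(dose_event(800, "saliva_bolus", start = 0),
                             dose_event(800, "saliva_bolus", start = 30)),
                     grid = g)
  i30 <- which(s$times == 30)
  expect_gt(s$C_S[i30], s$C_S[i30 - 1])  # jump applied at the event time
  expect_lt(max(abs(mass_balance(s)$relative_error)), 1e-6)
})
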