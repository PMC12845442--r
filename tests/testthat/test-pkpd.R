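test_that("time above MIC with interpolated crossings", {
  # constant profile above MIC: full interval
  p1 <- concentration_profile(seq(0, 100, 10), rep(4, 11))
  expect_equal(t_above_mic(p1, 2)$minutes, 100)
  expect_equal(t_above_mic(p1, 2)$fraction, 1)

  # linear decline from 2*MIC to 0: crossing at midpoint
  p2 <- concentration_profile(c(0, 100), c(4, 0))
  expect_equal(t_above_mic(p2, 2)$minutes, 50)

  expect_error(t_above_mic(p1, 0), "MIC")
})

test_that("multi-excursion T>MIC matches a dense-grid oracle", {
  t <- seq(0, 200, by = 5)
  conc <- 3 * exp(-((t - 40) / 18)^2) + 2.4 * exp(-((t - 140) / 12)^2)
  prof <- concentration_profile(t, conc)
  got <- t_above_mic(prof, 1.5)$minutes
  # brute force on a 1e6-point refinement of the piecewise-linear profile
  tt <- seq(0, 200, length.out = 1e6)
  cc <- stats::approx(t, conc, xout = tt)$y
  brute <- mean(cc > 1.5) * 200
  expect_lt(abs(got - brute), 0.01)
})

test_that("trapezoidal AUC: constant, exponential and refinement behaviour", {
  pc <- concentration_profile(seq(0, 50, 5), rep(3, 11))
  expect_equal(auc(pc), 150)
  expect_equal(auc(pc, c(10, 30)), 60)

  k <- 0.05; C0 <- 10; T <- 100
  closed <- C0 / k * (1 - exp(-k * T))
  coarse <- concentration_profile(seq(0, T, length.out = 51),
                                  C0 * exp(-k * seq(0, T, length.out = 51)))
  fine <- concentration_profile(seq(0, T, length.out = 2001),
                                C0 * exp(-k * seq(0, T, length.out = 2001)))
  expect_rel_equal(auc(fine), closed, 1e-3)
  # trapezoid overestimates a convex decay; refinement moves toward truth
  expect_lt(abs(auc(fine) - closed), abs(auc(coarse) - closed))
  expect_error(auc(pc, c(30, 30)), "empty")
  expect_error(auc(pc, c(-5, 20)), "span")
})

test_that("Hill effect: half-maximum, saturation and substitution", {
  expect_equal(hill_effect(2, Emax = 6, EC50 = 2, h = 1.7), 3)
  expect_equal(hill_effect(0, 6, 2), 0)
  expect_rel_equal(hill_effect(1e9, 6, 2, 1), 6, 1e-6)
  expect_equal(hill_effect(3, Emax = 1, EC50 = 1, h = 1), 0.75)
})

test_that("pkpd summary satisfies its invariants on a simulated profile", {
  b <- bateman_concentration(2000, 1, 500, 0.1, 0.02, seq(0, 300, 2))
  prof <- concentration_profile(seq(0, 300, 2), b$concentration)
  s <- pkpd_summary(prof, MIC = 0.5)
  expect_true(all(prof$concentrations <= s$Cmax))
  expect_lte(s$T_above_MIC_min, 300)
  expect_gte(s$T_above_MIC_min, 0)
  expect_equal(s$Cmax_over_MIC, s$Cmax / 0.5)
  expect_equal(s$AUC_over_MIC, s$AUC / 0.5)
  expect_equal(s$Tmax, prof$times[which.max(prof$concentrations)])
})

test_that("indirect response: flat baseline, full inhibition and steady state", {
  par <- effect_model_params(k_in = 2, k_out = 0.05, Imax = 1, IC50 = 1, h = 1)
  t10 <- 10 / par$k_out   # ten turnover times
  times <- seq(0, t10, length.out = 200)

  # drug-free: biomarker stays at baseline
  zero <- concentration_profile(c(0, t10), c(0, 0))
  r0 <- indirect_response(zero, par, "inhibit_production", times)
  expect_lt(max(abs(r0$R - par$R0)) / par$R0, 1e-6)

  # C >> IC50, Imax = 1: production fully off, R decays exp(-k_out t)
  big <- concentration_profile(c(0, t10), c(1e9, 1e9))
  r1 <- indirect_response(big, par, "inhibit_production", times)
  expect_lt(max(abs(r1$R - par$R0 * exp(-par$k_out * times))) / par$R0, 1e-6)

  # constant moderate C: new steady state R0 (1 - Imax C/(IC50 + C));
  # after ten turnover times a transient of order exp(-10) remains
  C <- 3
  mid <- concentration_profile(c(0, t10), c(C, C))
  r2 <- indirect_response(mid, par, "inhibit_production", times)
  expect_rel_equal(r2$R[length(times)], par$R0 * (1 - C / (1 + C)), 1e-3)

  # stimulate_loss mode lowers the biomarker as well
  r3 <- indirect_response(mid, effect_model_params(Emax = 2, EC50 = 1,
                                                   k_in = 2, k_out = 0.05),
                          "stimulate_loss", times)
  expect_lt(r3$R[length(times)], par$R0)
  expect_error(indirect_response(mid, par, "both"), "arg")
})

test_that("effect compartment: closed form, fast-equilibration and lagging peak", {
  t_span <- 100
  times <- seq(0, t_span, 0.5)
  const <- concentration_profile(c(0, t_span), c(5, 5))
  ce <- effect_compartment(const, k_e0 = 0.07, times)
  expect_equal(ce$Ce, 5 * (1 - exp(-0.07 * times)), tolerance = 1e-6)

  # k_e0 >> 1/t_span: effect site tracks the concentration
  b <- bateman_concentration(1000, 1, 500, 0.2, 0.03, times)
  prof <- concentration_profile(times, b$concentration)
  fast <- effect_compartment(prof, k_e0 = 1000 / t_span, times)
  i <- times > 10
  expect_lt(max(abs(fast$Ce[i] - prof$concentrations[i]) /
                  prof$concentrations[i]), 0.01)

  # hysteresis: Ce peaks later than C for unimodal profiles
  for (k_a in c(0.05, 0.1, 0.3)) {
    bb <- bateman_concentration(1000, 1, 500, k_a, 0.02, times)
    pp <- concentration_profile(times, bb$concentration)
    cc <- effect_compartment(pp, k_e0 = 0.05, times)
    expect_gt(times[which.max(cc$Ce)], times[which.max(pp$concentrations)],
              label = paste("k_a =", k_a))
  }
})

test_that("bacterial kill: growth, stasis, and T>MIC drives log reduction", {
  kg <- 0.005
  par <- effect_model_params(Emax = 2 * kg, EC50 = 1, h = 1)
  times <- seq(0, 1000, 5)

  zero <- concentration_profile(c(0, 1000), c(0, 0))
  g <- bacterial_kill(zero, par, kg, N0 = 1e6, times)
  expect_rel_equal(g$trajectory$log10_cfu[length(times)],
                   (log(1e6) + kg * 1000) / log(10), 1e-6)
  expect_equal(g$log10_reduction, 0, tolerance = 1e-8)

  # at C = EC50 the kill rate exactly balances growth: stasis
  stasis <- concentration_profile(c(0, 1000), c(1, 1))
  s <- bacterial_kill(stasis, par, kg, N0 = 1e6, times)
  expect_lt(max(abs(s$trajectory$log10_cfu - 6)), 1e-8)

  # exposure-response: longer T>MIC gives larger kill, strong rank correlation
  set.seed(99)
  k_el <- runif(12, 0.005, 0.08)
  res <- t(vapply(k_el, function(k) {
    conc <- bateman_concentration(4000, 1, 500, 0.1, k, times)$concentration
    prof <- concentration_profile(times, conc)
    kill <- bacterial_kill(prof, par, kg, N0 = 1e6, times)
    c(tam = t_above_mic(prof, 1)$minutes, red = kill$log10_reduction)
  }, c(tam = 0, red = 0)))
  expect_gt(stats::cor(res[, "tam"], res[, "red"], method = "spearman"), 0.8)
})
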