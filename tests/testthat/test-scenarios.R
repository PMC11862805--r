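skewed <- gamma_preset(0.049)
unif <- biomarker_dist("uniform", lower = 0, upper = 100)

test_that("marginal ORR reduces to the constant-curve value for flat truths", {
  cf <- aksa:::new_scenario_coefficients(qlogis(0.4), 0, 0, 0)
  expect_equal(marginal_orr(cf, 0, skewed), 0.4, tolerance = 1e-6)
  expect_equal(marginal_orr(cf, 1, unif), 0.4, tolerance = 1e-6)
  cf2 <- aksa:::new_scenario_coefficients(qlogis(0.4), qlogis(0.6) - qlogis(0.4), 0, 0)
  expect_equal(marginal_orr(cf2, 1, skewed), 0.6, tolerance = 1e-6)
  expect_equal(marginal_orr(cf2, 0, skewed), 0.4, tolerance = 1e-6)
})

test_that("flat and treatment-only null scenarios solve in closed form", {
  sp <- scenario_spec("NPNPNT", unif, 0.4, 0.4)
  cf <- solve_coefficients(sp)
  expect_equal(cf$b0, qlogis(0.4))
  expect_equal(c(cf$b1, cf$b2, cf$b3), c(0, 0, 0))
  sp2 <- scenario_spec("NPNPT", unif, 0.4, 0.6)
  cf2 <- solve_coefficients(sp2)
  expect_equal(cf2$b0, qlogis(0.4), tolerance = 1e-10)
  expect_equal(cf2$b1, qlogis(0.6) - qlogis(0.4), tolerance = 1e-10)
})

test_that("predictive and prognostic effects have the right structure", {
  cf_flat <- aksa:::new_scenario_coefficients(0.2, 0.5, 0, 0)
  eff <- predictive_prognostic_effects(cf_flat, unif, 50)
  expect_equal(eff$predictive, 0, tolerance = 1e-8)
  expect_equal(eff$prognostic, 0, tolerance = 1e-8)
  cf_prog <- aksa:::new_scenario_coefficients(0, 0, 0, 0.05)
  eff2 <- predictive_prognostic_effects(cf_prog, unif, 50)
  expect_equal(eff2$predictive, 0, tolerance = 1e-8)
  expect_gt(eff2$prognostic, 0)
  expect_error(predictive_prognostic_effects(cf_prog, unif, 150), "zero mass")
})

test_that("solved alternative scenarios reproduce their targets (quadrature + MC oracle)", {
  cases <- list(list(lab = "HPNP_40", dist = skewed, delta = 0.40),
                list(lab = "LPNP_20", dist = unif, delta = 0.20))
  for (cs in cases) {
    sp <- scenario_spec(cs$lab, cs$dist, 0.4, 0.6, predictive_effect = cs$delta)
    cf <- solve_coefficients(sp)
    expect_equal(marginal_orr(cf, 0, cs$dist), 0.4, tolerance = 1e-4)
    expect_equal(marginal_orr(cf, 1, cs$dist), 0.6, tolerance = 1e-4)
    eff <- predictive_prognostic_effects(cf, cs$dist, cf$true_cutoff)
    expect_lt(abs(eff$predictive - cs$delta), 1e-3)
    # independent sampling oracle at 1e6 draws
    expect_equal(mc_orr(cf, 0, cs$dist), 0.4, tolerance = 1e-3)
    expect_equal(mc_orr(cf, 1, cs$dist), 0.6, tolerance = 1e-3)
    expect_equal(mc_predictive(cf, cs$dist, cf$true_cutoff), cs$delta,
                 tolerance = 2e-3)
    # arm curves intersect at the true cutoff
    p1 <- plogis(cf$b0 + cf$b1 + (cf$b2 + cf$b3) * cf$true_cutoff)
    p0 <- plogis(cf$b0 + cf$b3 * cf$true_cutoff)
    expect_equal(p1, p0, tolerance = 1e-10)
  }
})

test_that("prognostic variants keep the ORRs, the slope and b3 = kappa*b2", {
  base <- solve_coefficients(scenario_spec("MPNP_30", unif, 0.4, 0.6,
                                           predictive_effect = 0.3))
  for (kappa in c(0.2, 0.5)) {
    sp <- scenario_spec("MPXP_30", unif, 0.4, 0.6, predictive_effect = 0.3,
                        prognostic_fraction = kappa)
    cf <- solve_coefficients(sp)
    expect_equal(cf$b2, base$b2, tolerance = 1e-10)
    expect_equal(cf$b3, kappa * cf$b2, tolerance = 1e-12)
    expect_equal(marginal_orr(cf, 0, unif), 0.4, tolerance = 1e-6)
    expect_equal(marginal_orr(cf, 1, unif), 0.6, tolerance = 1e-6)
    expect_lt(cf$realized_predictive, 0.3 + 1e-6)
  }
})

test_that("prognostic null scenarios hit the magnitude constraint at cutoff 17", {
  sp <- scenario_spec("NPPT", skewed, 0.4, 0.6, prognostic_magnitude = 0.2,
                      fixed_cutoff = 17)
  cf <- solve_coefficients(sp)
  expect_equal(cf$b2, 0)
  expect_equal(marginal_orr(cf, 0, skewed), 0.4, tolerance = 1e-6)
  expect_equal(marginal_orr(cf, 1, skewed), 0.6, tolerance = 1e-6)
  eff <- predictive_prognostic_effects(cf, skewed, 17)
  expect_equal(eff$prognostic, 0.2, tolerance = 1e-6)
})

test_that("step truth solves the four cell probabilities in closed form", {
  sp <- scenario_spec("HPNP_50", unif, 0.4, 0.6, predictive_effect = 0.5,
                      truth_form = "step")
  cf <- solve_coefficients(sp)
  p <- cf$step_params
  q <- bm_cdf(unif, p$cutoff)
  expect_equal(q * p$p0_below + (1 - q) * p$p0_above, 0.4, tolerance = 1e-12)
  expect_equal(q * p$p1_below + (1 - q) * p$p1_above, 0.6, tolerance = 1e-12)
  expect_equal((p$p1_above - p$p0_above) - (p$p1_below - p$p0_below), 0.5,
               tolerance = 1e-12)
  expect_equal(p$p0_above, p$p0_below)
  expect_equal(marginal_orr(cf, 1, unif), 0.6, tolerance = 1e-12)
})

test_that("trial simulation is reproducible with exact arm counts", {
  sp <- scenario_spec("NPNPT", unif, 0.4, 0.6, n1 = 40, n0 = 20)
  cf <- solve_coefficients(sp)
  d1 <- simulate_trial(cf, sp, seed = 99)
  d2 <- simulate_trial(cf, sp, seed = 99)
  expect_identical(d1, d2)
  expect_equal(unname(arm_sizes(d1)), c(40, 20))
  # Bernoulli(1/2) concentration at large n
  sp_big <- scenario_spec("NPNPNT", unif, 0.5, 0.5, n1 = 5000, n0 = 5000)
  cf_big <- aksa:::new_scenario_coefficients(0, 0, 0, 0)
  d_big <- simulate_trial(cf_big, sp_big, seed = 3)
  expect_equal(mean(d_big$response), 0.5, tolerance = 0.015)
})

test_that("the preset grid covers the scenario families and distributions", {
  specs <- preset_scenarios()
  expect_length(specs, 16 * 4)
  labs <- unique(vapply(specs, function(s) s$label, character(1)))
  expect_true(all(null_labels() %in% labs))
  expect_true(all(c("HPNP_50", "HPMP_50", "HPHP_50", "LPHP_20") %in% labs))
  nulls <- preset_scenarios(labels = null_labels())
  expect_length(nulls, 16)
  expect_true("NPPT.uniform" %in% names(nulls))
  expect_error(preset_scenarios(labels = "XXX"), "unknown scenario label")
  g <- preset_scenarios(labels = "NPNPNT")[["NPNPNT.skewed"]]
  expect_equal(g$dist$shape, 650.54 * 0.049^2)
})
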