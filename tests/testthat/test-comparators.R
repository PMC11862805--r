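sim_null_trial <- function(seed, n = 400, b1 = 0.4) {
  set.seed(seed)
  arm <- rep(c(1L, 0L), length.out = n)
  x <- runif(n, 0, 100)
  p <- plogis(-0.4 + b1 * arm + 0.005 * x)
  trial_data(seq_len(n), arm, x, rbinom(n, 1, p))
}

test_that("interaction test is deterministic, calibrated under the null and powered", {
  td <- sim_null_trial(1)
  expect_identical(interaction_test(td)$metric, interaction_test(td)$metric)
  reject <- vapply(1:2000, function(i)
    interaction_test(sim_null_trial(5000 + i))$metric < 0.05, logical(1))
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
  strong <- strong_effect_trial(seed = 2, n1 = 600, n0 = 300)
  expect_lt(interaction_test(strong)$metric, 0.001)
})

test_that("dichotomised interaction test minimises over the feasible grid", {
  td <- strong_effect_trial(seed = 6)
  grid <- cutoff_grid(td)
  res <- interaction_test_dichotomised(td, grid)
  per_cutoff <- vapply(grid, function(c)
    interaction_test_dichotomised(td, grid = c)$metric, numeric(1))
  expect_equal(res$metric, min(per_cutoff), tolerance = 1e-12)
  expect_true(res$diagnostics$selected_cutoff %in% grid)
  one <- interaction_test_dichotomised(td, grid = grid[3])
  expect_equal(one$metric, per_cutoff[3])
})

test_that("ITD metric is invariant to monotone biomarker transforms on a quantile grid", {
  td <- strong_effect_trial(seed = 14)
  res <- interaction_test_dichotomised(td)
  td2 <- td
  td2$biomarker <- log1p(td$biomarker)      # strictly monotone
  res2 <- interaction_test_dichotomised(td2)
  expect_equal(res$metric, res2$metric, tolerance = 1e-10)
})

test_that("ITD recovers a step-truth cutoff near the jump", {
  hits <- vapply(1:200, function(i) {
    set.seed(i)
    x <- runif(60, 0, 100)
    arm <- rep(c(1L, 0L), c(40, 20))
    p <- ifelse(arm == 1 & x > 50, 0.9, ifelse(arm == 1, 0.15, 0.4))
    td <- trial_data(1:60, arm, x, rbinom(60, 1, p))
    res <- interaction_test_dichotomised(td)
    sel <- res$diagnostics$selected_cutoff
    grid <- cutoff_grid(td)
    !is.null(sel) && min(abs(sel - 50)) <= max(diff(sort(c(grid, 50))))
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("likelihood-ratio test matches the chi-squared tail and nests properly", {
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  for (seed in 1:10) {
    td <- sim_null_trial(seed, n = 80)
    res <- likelihood_ratio_test(td)
    expect_gte(res$diagnostics$lr_statistic, 0)
    expect_equal(res$metric,
                 pchisq(res$diagnostics$lr_statistic, 1, lower.tail = FALSE))
  }
  # asymptotic equivalence with the Wald interaction p-value
  big <- strong_effect_trial(seed = 100, n1 = 50000, n0 = 50000)
  expect_equal(likelihood_ratio_test(big)$metric,
               interaction_test(big)$metric, tolerance = 0.01)
})

test_that("cutoff step fit uses side means and the beta posterior tail", {
  # deterministic fixture with a hard step at 50
  x <- c(seq(5, 45, by = 5), seq(55, 95, by = 5))
  td <- trial_data(1:36, rep(c(1L, 0L), 18),
                   rep(x, each = 2),
                   as.integer(rep(x, each = 2) > 50 & rep(c(1L, 0L), 18) == 1L))
  res <- cutoff_probability(td, n_draws = 10000, seed = 31)
  expect_gt(res$metric, 0.99)
  expect_gt(res$diagnostics$selected_cutoff, 40)
  expect_lt(res$diagnostics$selected_cutoff, 60)
  # identical response pattern in both arms is symmetric around 1/2
  td_sym <- trial_data(1:40, rep(c(1L, 0L), 20), rep(seq(2.5, 97.5, 5), each = 2),
                       rep(rep(c(0L, 1L), each = 2), 10))
  res_sym <- cutoff_probability(td_sym, n_draws = 10000, seed = 8)
  expect_equal(res_sym$metric, 0.5, tolerance = 3 / sqrt(10000))
})

test_that("per-arm AUC equals the exhaustive Mann-Whitney proportion", {
  # 12-patient fixture, one arm, with ties
  x_cases <- c(3, 5, 7, 7, 2)
  x_controls <- c(1, 2, 4, 7, 6, 2, 5)
  expect_equal(aksa:::auc_components(x_cases, x_controls)$auc,
               auc_brute(x_cases, x_controls))
  expect_equal(aksa:::auc_components(c(3, 5), c(1, 2))$auc, 1)
  expect_equal(aksa:::auc_components(c(4, 4), c(4, 4, 4))$auc, 0.5)
})

test_that("DeLong test agrees with the pROC unpaired reference", {
  skip_if_not_installed("pROC")
  for (seed in c(3, 17, 29)) {
    td <- strong_effect_trial(seed = seed)
    res <- delong_test(td)
    r1 <- pROC::roc(td$response[td$arm == 1], td$biomarker[td$arm == 1],
                    direction = "<", levels = c(0, 1), quiet = TRUE)
    r0 <- pROC::roc(td$response[td$arm == 0], td$biomarker[td$arm == 0],
                    direction = "<", levels = c(0, 1), quiet = TRUE)
    ref <- pROC::roc.test(r1, r0, method = "delong", paired = FALSE,
                          alternative = "greater")
    expect_equal(res$diagnostics$auc1, as.numeric(pROC::auc(r1)), tolerance = 1e-12)
    expect_equal(res$diagnostics$auc0, as.numeric(pROC::auc(r0)), tolerance = 1e-12)
    expect_equal(res$metric, ref$p.value, tolerance = 1e-9)
  }
})

test_that("DeLong one-sided p-values of opposite hypotheses sum to one", {
  td <- strong_effect_trial(seed = 44)
  res <- delong_test(td)
  rev <- td
  rev$arm <- 1L - rev$arm
  res_rev <- delong_test(rev)
  expect_equal(res$metric + res_rev$metric, 1, tolerance = 1e-10)
})

test_that("degenerate arms are flagged with no-evidence metrics", {
  td <- trial_data(1:20, rep(c(1L, 0L), c(10, 10)), runif(20, 0, 100),
                   rep(c(1L, 0L), c(12, 8)))  # arm 1 has responders only
  res <- delong_test(td)
  expect_true(res$flagged)
  expect_equal(res$metric, 1)
})

test_that("analyze_trial returns one result per requested method", {
  td <- strong_effect_trial(seed = 50)
  out <- analyze_trial(td, methods = "all", B = 500, n_perm = 100,
                       n_draws = 500, seed = 1)
  expect_named(out, c("it", "itd", "lr", "stepp", "cutoff", "delong", "aksa"))
  for (r in out) {
    expect_s3_class(r, "method_result")
    expect_gte(r$metric, 0)
    expect_lte(r$metric, 1)
  }
})
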