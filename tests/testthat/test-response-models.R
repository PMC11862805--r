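make_fit_data <- function(n = 400, b = c(-0.4, 0.3, 0.02, 0.01), seed = 1) {
  set.seed(seed)
  arm <- rep(c(1L, 0L), length.out = n)
  x <- runif(n, 0, 100)
  p <- plogis(b[1] + b[2] * arm + b[3] * arm * x + b[4] * x)
  trial_data(seq_len(n), arm, x, rbinom(n, 1, p))
}

test_that("logistic interaction fit matches an independent IRLS oracle", {
  td <- make_fit_data(n = 500, seed = 21)
  fit <- fit_logistic_interaction(td)
  X <- cbind(1, td$arm, td$biomarker, td$arm * td$biomarker)
  beta_oracle <- irls_logistic(X, td$response)
  expect_equal(unname(fit$coefficients), beta_oracle, tolerance = 1e-6)
  expect_false(fit$separated)
  expect_false(fit$rank_deficient)
  # covariance symmetric PSD, se >= 0
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-12)
  expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > -1e-10))
})

test_that("large-n estimates are consistent for the generating coefficients", {
  b <- c(-0.4, 0.3, 0.02, 0.005)
  td <- make_fit_data(n = 100000, b = b, seed = 8)
  fit <- fit_logistic_interaction(td)
  # design order is (intercept, arm, biomarker, arm:biomarker)
  expect_equal(unname(fit$coefficients), b[c(1, 2, 4, 3)], tolerance = 0.05)
})

test_that("degenerate designs are flagged, not thrown", {
  td <- trial_data(1:40, rep(c(1L, 0L), 20), rep(50, 40),
                   rep(c(1L, 0L, 0L, 1L), 10))
  fit <- fit_logistic_interaction(td)
  expect_true(fit$rank_deficient)
  expect_equal(interaction_pvalue(fit), 1)
})

test_that("interaction log-likelihood dominates the nested model", {
  for (seed in 1:5) {
    td <- make_fit_data(n = 80, seed = seed)
    full <- fit_logistic_interaction(td)
    nested <- aksa:::fit_logistic_main(td)
    expect_gte(full$loglik, nested$loglik - 1e-8)
  }
})

test_that("predict_logit returns the design-vector delta-method se", {
  td <- make_fit_data(n = 200, seed = 4)
  fit <- fit_logistic_interaction(td)
  # x = 0, arm 0 picks out the intercept
  pr <- predict_logit(fit, 0, 0)
  expect_equal(pr$estimate, unname(fit$coefficients[1]))
  expect_equal(pr$se, sqrt(fit$vcov[1, 1]))
  # general point: agree with stats::glm reference prediction
  ref <- glm(response ~ arm * biomarker, binomial(), data = td)
  nd <- data.frame(arm = 1L, biomarker = c(10, 42.5, 90))
  rp <- predict(ref, nd, type = "link", se.fit = TRUE)
  pr1 <- predict_logit(fit, 1, c(10, 42.5, 90))
  expect_equal(pr1$estimate, unname(rp$fit), tolerance = 1e-6)
  expect_equal(pr1$se, unname(rp$se.fit), tolerance = 1e-4)
  # arm difference at x equals b1 + b2*x for the linear backend
  x <- c(5, 50, 95)
  dc <- difference_curve(fit, x)
  expect_equal(dc$estimate,
               unname(fit$coefficients[2] + fit$coefficients[4] * x),
               tolerance = 1e-12)
})

test_that("additive covariates are carried and cancel in the difference curve", {
  set.seed(61)
  n <- 200
  arm <- rep(c(1L, 0L), n / 2)
  x <- runif(n, 0, 100)
  z <- rnorm(n)
  p <- plogis(-0.4 + 0.3 * arm + 0.02 * arm * x + 0.5 * z)
  td <- trial_data(1:n, arm, x, rbinom(n, 1, p), covariates = data.frame(z = z))
  fit <- fit_logistic_interaction(td, covariates = TRUE)
  expect_length(fit$coefficients, 5)
  dc <- difference_curve(fit, c(20, 60))
  expect_equal(dc$estimate,
               unname(fit$coefficients[2] + fit$coefficients[4] * c(20, 60)),
               tolerance = 1e-10)
})

test_that("Wald p-value matches the normal tail formula", {
  td <- make_fit_data(n = 300, seed = 12)
  fit <- fit_logistic_interaction(td)
  b2 <- fit$coefficients[["arm:biomarker"]]
  se <- sqrt(fit$vcov["arm:biomarker", "arm:biomarker"])
  expect_equal(interaction_pvalue(fit), 2 * (1 - pnorm(abs(b2) / se)),
               tolerance = 1e-12)
})

test_that("GAM backend honours the basis dimension and tracks a linear truth", {
  td <- make_fit_data(n = 300, b = c(-0.5, 0.2, 0.03, 0), seed = 30)
  gfit <- fit_gam_interaction(td, basis_dim = 3)
  expect_equal(gfit$backend, "gam")
  sm <- gfit$gam$smooth[[1]]
  expect_equal(sm$bs.dim, 3)
  lfit <- fit_logistic_interaction(td)
  xs <- quantile(td$biomarker, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  dg <- difference_curve(gfit, xs)
  dl <- difference_curve(lfit, xs)
  expect_true(all(abs(dg$estimate - dl$estimate) <= 2 * (dg$se + dl$se)))
})

test_that("GAM difference curve increases on a strong monotone fixture", {
  td <- strong_effect_trial(seed = 77, n1 = 120, n0 = 60)
  gfit <- fit_gam_interaction(td, basis_dim = 3)
  xs <- quantile(td$biomarker, seq(0.1, 0.9, 0.1), names = FALSE)
  dc <- difference_curve(gfit, xs)
  expect_gt(dc$estimate[9], dc$estimate[1])
})

test_that("interaction Wald p-value is calibrated under b2 = 0", {
  reject <- vapply(1:2000, function(i) {
    td <- make_fit_data(n = 400, b = c(-0.4, 0.4, 0, 0.005), seed = 10000 + i)
    interaction_pvalue(fit_logistic_interaction(td)) < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})
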