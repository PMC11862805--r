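# Independent oracles used to freeze expected values.  Each is written
# from first principles, deliberately not sharing code with the package.

# logistic regression by plain iteratively-reweighted least squares
irls_logistic <- function(X, y, max_iter = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.numeric(beta)
}

# empirical AUC by exhaustive enumeration of (responder, non-responder)
# pairs, ties counted one half
auc_brute <- function(x_cases, x_controls) {
  total <- 0
  for (a in x_cases) for (b in x_controls)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(x_cases) * length(x_controls))
}

# STEPP permutation p-value by exhaustive enumeration over all distinct
# arm-label assignments (small n only), using the package statistic
stepp_p_exhaustive <- function(data, r1, r2) {
  win <- stepp_windows(data, r1, r2)
  S_obs <- stepp_statistic(win, data)$S
  n <- nrow(data)
  n1 <- sum(data$arm == 1)
  combs <- utils::combn(n, n1)
  S_all <- apply(combs, 2, function(idx) {
    arm <- integer(n)
    arm[idx] <- 1L
    d2 <- data
    d2$arm <- arm
    tryCatch(stepp_statistic(win, d2)$S, error = function(e) NA_real_)
  })
  S_all <- S_all[!is.na(S_all)]
  mean(S_all >= S_obs - 1e-12)
}

# deterministic small trial fixture with a strong monotone effect in the
# experimental arm only
strong_effect_trial <- function(seed = 42, n1 = 40, n0 = 20) {
  set.seed(seed)
  x <- c(runif(n1, 0, 100), runif(n0, 0, 100))
  arm <- rep(c(1L, 0L), c(n1, n0))
  p <- ifelse(arm == 1L, plogis(-3 + 0.08 * x), 0.4)
  trial_data(seq_along(x), arm, x, rbinom(n1 + n0, 1, p))
}

# Monte-Carlo oracle for marginal / conditional response-rate targets
mc_orr <- function(coeffs, arm, dist, n = 1e6, seed = 7) {
  set.seed(seed)
  x <- bm_sample(dist, n)
  p <- plogis(coeffs$b0 + coeffs$b1 * arm + coeffs$b2 * x * arm + coeffs$b3 * x)
  mean(p)
}

mc_predictive <- function(coeffs, dist, cutoff, n = 1e6, seed = 7) {
  set.seed(seed)
  x <- bm_sample(dist, n)
  p1 <- plogis(coeffs$b0 + coeffs$b1 + (coeffs$b2 + coeffs$b3) * x)
  p0 <- plogis(coeffs$b0 + coeffs$b3 * x)
  above <- x > cutoff
  (mean(p1[above]) - mean(p0[above])) - (mean(p1[!above]) - mean(p0[!above]))
}
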