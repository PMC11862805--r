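#' The AKSA predictiveness test
#'
#' AKSA (Average Kolmogorov-Smirnov inspired Approach) asks whether the
#' logit-scale difference between the experimental and control
#' biomarker-response curves tends to increase with the biomarker.  For
#' each of `B` sampled couples of biomarker values `(x1, x2)` with
#' `x1 <= x2` it draws one value from
#' `N(mu_i, sigma_i)` where `mu_i = D(x2) - D(x1)` is the estimated
#' increase of the difference curve and `sigma_i` its root-sum-square
#' standard error, and reports the fraction of positive draws
#' `P(D_X > 0)`.  The biomarker is declared predictive when this
#' probability exceeds a pre-specified threshold (0.74 at the default
#' 15% type-I error calibration).
#'
#' @name aksa
NULL

#' Estimated difference curve between the arm response models
#'
#' `D(x)` is the arm-1 minus arm-0 logit-scale prediction at `x`; its
#' standard error is `sqrt(se1(x)^2 + se0(x)^2)`, treating the two arm
#' predictions as independent.
#'
#' @param model a fitted `response_fit`.
#' @param x numeric vector of biomarker values.
#' @return data.frame with columns `x`, `estimate`, `se`.
#' @export
difference_curve <- function(model, x) {
  p1 <- predict_logit(model, 1, x)
  p0 <- predict_logit(model, 0, x)
  data.frame(x = x, estimate = p1$estimate - p0$estimate,
             se = sqrt(p1$se^2 + p0$se^2))
}

#' Sample couples of biomarker values
#'
#' Draws `B` pairs independently with replacement from the observed
#' biomarker values (numeric source) or from a parametric
#' [biomarker_dist()], orders each pair so `x1 <= x2`, and optionally
#' enforces a minimum gap `x2 - x1 > min_gap` by resampling offending
#' pairs (bounded retries).
#'
#' @param source numeric vector of observed values, or a
#'   [biomarker_dist()].
#' @param B number of couples.
#' @param min_gap minimum gap `t >= 0`.
#' @param max_retries resampling rounds before giving up.
#' @return a `B x 2` matrix with columns `x1`, `x2`.
#' @export
sample_couples <- function(source, B, min_gap = 0, max_retries = 1000) {
  stopifnot(B >= 1, min_gap >= 0)
  draw <- function(n) {
    if (inherits(source, "biomarker_dist")) bm_sample(source, n)
    else sample(source, n, replace = TRUE)
  }
  if (!inherits(source, "biomarker_dist")) {
    stopifnot(is.numeric(source), length(source) >= 1)
    if (min_gap > 0 && (max(source) - min(source)) <= min_gap)
      stop("source range cannot satisfy the minimum gap")
  }
  x1 <- draw(B); x2 <- draw(B)
  lo <- pmin(x1, x2); hi <- pmax(x1, x2)
  if (min_gap > 0) {
    for (k in seq_len(max_retries)) {
      bad <- which(hi - lo <= min_gap)
      if (!length(bad)) break
      a <- draw(length(bad)); b <- draw(length(bad))
      lo[bad] <- pmin(a, b); hi[bad] <- pmax(a, b)
    }
    if (any(hi - lo <= min_gap))
      stop("could not satisfy the minimum gap after bounded retries")
  }
  cbind(x1 = lo, x2 = hi)
}

## mu_i = D(x2) - D(x1), sigma_i = sqrt(s(x1)^2 + s(x2)^2).  For the
## linear backend both are closed forms in the coefficients: D(x) =
## b1 + b2*x and s(x)^2 = d1'Vd1 + d0'Vd0 is a quadratic in x, which
## avoids building B x 4 design matrices inside simulation loops.
aksa_mu_sigma <- function(model, couples) {
  if (model$backend == "linear_logistic" && length(model$coefficients) == 4 &&
      !anyNA(model$coefficients)) {
    V <- model$vcov
    b2 <- model$coefficients[[4]]
    s2 <- function(x)
      (2 * V[1, 1] + V[2, 2] + 2 * V[1, 2]) +
      2 * x * (2 * V[1, 3] + V[1, 4] + V[2, 3] + V[2, 4]) +
      x^2 * (2 * V[3, 3] + V[4, 4] + 2 * V[3, 4])
    mu <- b2 * (couples[, 2] - couples[, 1])
    sigma <- sqrt(s2(couples[, 1]) + s2(couples[, 2]))
  } else {
    d2 <- difference_curve(model, couples[, 2])
    d1 <- difference_curve(model, couples[, 1])
    mu <- d2$estimate - d1$estimate
    sigma <- sqrt(d1$se^2 + d2$se^2)
  }
  list(mu = mu, sigma = sigma)
}

#' Monte-Carlo probability that the difference curve increases
#'
#' For each couple, `mu_i = D(x2) - D(x1)` and
#' `sigma_i = sqrt(s(x1)^2 + s(x2)^2)` are computed from the fitted
#' model, one draw `d_i ~ N(mu_i, sigma_i)` is taken, and the probability
#' is the exact fraction of positive draws.  A flagged model (separation)
#' or non-finite `mu`/`sigma` yields the no-evidence value 0.5.
#'
#' @param model a fitted `response_fit`.
#' @param couples matrix from [sample_couples()].
#' @param seed optional integer seed for the normal draws.
#' @return object of class `aksa_result` with elements `probability`,
#'   `B`, `mu`, `sigma`, `draws`, `flagged`.
#' @export
aksa_probability <- function(model, couples, seed = NULL) {
  stopifnot(is.matrix(couples), ncol(couples) == 2, nrow(couples) >= 1)
  flagged <- isTRUE(model$separated) || isTRUE(model$rank_deficient)
  if (!flagged) {
    ms <- aksa_mu_sigma(model, couples)
    mu <- ms$mu
    sigma <- ms$sigma
    flagged <- any(!is.finite(mu)) || any(!is.finite(sigma))
  }
  if (flagged) {
    return(structure(list(probability = 0.5, B = nrow(couples),
                          mu = NULL, sigma = NULL, draws = NULL,
                          flagged = TRUE), class = "aksa_result"))
  }
  maybe_seed(seed)
  draws <- stats::rnorm(length(mu), mu, sigma)
  structure(list(probability = sum(draws > 0) / length(draws),
                 B = length(draws), mu = mu, sigma = sigma, draws = draws,
                 flagged = FALSE), class = "aksa_result")
}

#' @export
print.aksa_result <- function(x, ...) {
  cat(sprintf("AKSA: P(D_X > 0) = %.4f from %d couples%s\n",
              x$probability, x$B, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Decision rule for an AKSA result
#'
#' Declares the biomarker predictive when the probability strictly
#' exceeds `alpha_aksa`.
#'
#' @param result an `aksa_result`.
#' @param alpha_aksa probability threshold in `(0, 1)`.
#' @return a [method_result()].
#' @export
aksa_decide <- function(result, alpha_aksa = default_thresholds()[["aksa"]]) {
  stopifnot(inherits(result, "aksa_result"))
  method_result("aksa", result$probability, alpha_aksa,
                direction = "reject_above",
                diagnostics = list(B = result$B), flagged = result$flagged)
}

#' Run the full AKSA test on a trial dataset
#'
#' Fits the requested response-model backend, samples `B` couples from
#' the observed biomarker values (or a supplied parametric source),
#' computes the Monte-Carlo probability and applies the decision rule.
#'
#' @param data a [trial_data()].
#' @param B number of couples (default 10000).
#' @param alpha_aksa decision threshold.
#' @param min_gap minimum couple gap `t`.
#' @param backend `"linear_logistic"` or `"gam"`.
#' @param couple_source `"empirical"` (observed values) or a
#'   [biomarker_dist()].
#' @param basis_dim GAM basis dimension.
#' @param seed optional integer seed (couples and draws).
#' @return a [method_result()]; diagnostics carry the probability, `B`
#'   and backend.
#' @export
aksa_test <- function(data, B = 10000, alpha_aksa = default_thresholds()[["aksa"]],
                      min_gap = 0, backend = c("linear_logistic", "gam"),
                      couple_source = "empirical", basis_dim = 3, seed = NULL) {
  backend <- match.arg(backend)
  maybe_seed(seed)
  model <- if (backend == "gam") fit_gam_interaction(data, basis_dim)
           else fit_logistic_interaction(data)
  src <- if (identical(couple_source, "empirical")) data$biomarker else couple_source
  couples <- sample_couples(src, B, min_gap)
  res <- aksa_probability(model, couples)
  out <- aksa_decide(res, alpha_aksa)
  out$diagnostics$backend <- backend
  out
}
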