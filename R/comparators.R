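#' Comparator tests for biomarker predictiveness
#'
#' Five established alternatives to the AKSA test, all sharing the
#' [trial_data()] contract and returning a [method_result()]: the Wald
#' interaction test (`it`), its dichotomised minimum-p variant (`itd`),
#' the likelihood-ratio test (`lr`), a Bayesian cutoff-probability rule
#' (`cutoff`) and the DeLong comparison of per-arm ROC areas (`delong`).
#' The STEPP permutation test lives in [stepp_test()].
#'
#' @name comparators
NULL

#' Quantile-based candidate cutoff grid
#'
#' Deciles 10%-90% of the observed biomarker values, filtered so that for
#' each candidate every arm-by-side cell contains at least `min_cell`
#' patients.  Quantile-based candidates make the dichotomised methods
#' invariant to monotone biomarker transformations.
#'
#' @param data a [trial_data()].
#' @param probs quantile probabilities.
#' @param min_cell minimum patients per arm-by-side cell.
#' @return numeric vector of feasible cutoffs (possibly empty).
#' @export
cutoff_grid <- function(data, probs = seq(0.1, 0.9, by = 0.1), min_cell = 2) {
  cand <- unique(stats::quantile(data$biomarker, probs, names = FALSE, type = 7))
  keep <- vapply(cand, function(c) {
    above <- data$biomarker > c
    all(c(sum(data$arm == 1 & above), sum(data$arm == 1 & !above),
          sum(data$arm == 0 & above), sum(data$arm == 0 & !above)) >= min_cell)
  }, logical(1))
  cand[keep]
}

#' Treatment-by-biomarker Wald interaction test
#'
#' Two-sided Wald p-value of the interaction coefficient in
#' `response ~ arm + biomarker + arm:biomarker`.  Separation or rank
#' deficiency gives the no-evidence metric 1, flagged.
#'
#' @param data a [trial_data()].
#' @param threshold decision threshold `alpha_IT`.
#' @return a [method_result()].
#' @export
interaction_test <- function(data, threshold = default_thresholds()[["it"]]) {
  fit <- fit_logistic_interaction(data)
  p <- interaction_pvalue(fit)
  method_result("it", p, threshold,
                diagnostics = list(coefficient = unname(fit$coefficients[["arm:biomarker"]])),
                flagged = fit$separated || fit$rank_deficient)
}

#' Interaction test with a dichotomised biomarker
#'
#' For each candidate cutoff `c` the model
#' `response ~ arm + 1(X > c) + arm:1(X > c)` is fitted and the Wald
#' p-value of the interaction term recorded; the metric is the minimum
#' p-value over the grid.  The selected cutoff is reported in the
#' diagnostics.
#'
#' @param data a [trial_data()].
#' @param grid candidate cutoffs; defaults to the feasible deciles of
#'   [cutoff_grid()].
#' @param threshold decision threshold `alpha_ITD`.
#' @return a [method_result()].
#' @export
interaction_test_dichotomised <- function(data, grid = NULL,
                                          threshold = default_thresholds()[["itd"]]) {
  grid <- grid %||% cutoff_grid(data)
  if (!length(grid))
    return(method_result("itd", 1, threshold,
                         diagnostics = list(reason = "empty feasible grid"),
                         flagged = TRUE))
  pvals <- vapply(grid, function(c) {
    ind <- as.numeric(data$biomarker > c)
    X <- cbind("(Intercept)" = 1, arm = data$arm, above = ind,
               "arm:above" = data$arm * ind)
    fit <- logistic_ml(X, data$response)
    b <- fit$coefficients[["arm:above"]]; s <- fit$se[["arm:above"]]
    if (fit$separated || fit$rank_deficient || !is.finite(b) ||
        !is.finite(s) || s <= 0) return(NA_real_)
    2 * stats::pnorm(-abs(b) / s)
  }, numeric(1))
  if (all(is.na(pvals)))
    return(method_result("itd", 1, threshold,
                         diagnostics = list(reason = "all candidates degenerate"),
                         flagged = TRUE))
  i <- which.min(pvals)
  method_result("itd", pvals[i], threshold,
                diagnostics = list(selected_cutoff = grid[i],
                                   n_candidates = length(grid)))
}

#' Likelihood-ratio test for the interaction term
#'
#' Compares `response ~ arm + biomarker` against
#' `response ~ arm + biomarker + arm:biomarker`; the metric is the
#' upper-tail chi-squared (1 df) p-value of twice the log-likelihood
#' difference.
#'
#' @param data a [trial_data()].
#' @param threshold decision threshold `alpha_LR`.
#' @return a [method_result()].
#' @export
likelihood_ratio_test <- function(data, threshold = default_thresholds()[["lr"]]) {
  full <- fit_logistic_interaction(data)
  nested <- fit_logistic_main(data)
  if (full$separated || full$rank_deficient || nested$separated)
    return(method_result("lr", 1, threshold,
                         diagnostics = list(reason = "flagged fit"),
                         flagged = TRUE))
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  method_result("lr", stats::pchisq(stat, df = 1, lower.tail = FALSE),
                threshold, diagnostics = list(lr_statistic = stat))
}

#' Cutoff-probability rule
#'
#' Selects the single shared cutoff minimising the summed
#' ordinary-least-squares residual of per-arm step functions (group means
#' below/above the cutoff, both arms), then computes the Monte-Carlo
#' probability that `(p1a - p0a) - (p1b - p0b) > 0` under independent
#' beta posteriors for the four cells.  The improper `Beta(0, 0)` prior
#' gives `Beta(y, n - y)` posteriors; boundary cells (`y = 0` or
#' `y = n`) fall back to Jeffreys `Beta(y + 1/2, n - y + 1/2)` and are
#' noted in the diagnostics.
#'
#' @param data a [trial_data()].
#' @param grid candidate cutoffs (defaults to [cutoff_grid()]).
#' @param n_draws posterior Monte-Carlo draws `M`.
#' @param threshold decision threshold `alpha_cutoff`.
#' @param seed optional integer seed for the posterior draws.
#' @return a [method_result()] (direction `reject_above`).
#' @export
cutoff_probability <- function(data, grid = NULL, n_draws = 10000,
                               threshold = default_thresholds()[["cutoff"]],
                               seed = NULL) {
  grid <- grid %||% cutoff_grid(data, min_cell = 1)
  if (!length(grid))
    return(method_result("cutoff", 0.5, threshold, direction = "reject_above",
                         diagnostics = list(reason = "empty feasible grid"),
                         flagged = TRUE))
  rss <- vapply(grid, function(c) {
    total <- 0
    for (k in c(0, 1)) {
      y <- data$response[data$arm == k]
      above <- data$biomarker[data$arm == k] > c
      for (side in c(TRUE, FALSE)) {
        ys <- y[above == side]
        if (length(ys)) total <- total + sum((ys - mean(ys))^2)
      }
    }
    total
  }, numeric(1))
  c_star <- grid[which.min(rss)]
  cell <- function(k, side_above) {
    sel <- data$arm == k & ((data$biomarker > c_star) == side_above)
    c(y = sum(data$response[sel]), n = sum(sel))
  }
  cells <- list(p1a = cell(1, TRUE), p1b = cell(1, FALSE),
                p0a = cell(0, TRUE), p0b = cell(0, FALSE))
  maybe_seed(seed)
  jeffreys <- character(0)
  post <- lapply(names(cells), function(nm) {
    y <- cells[[nm]][["y"]]; n <- cells[[nm]][["n"]]
    if (n == 0 || y == 0 || y == n) {
      jeffreys <<- c(jeffreys, nm)
      stats::rbeta(n_draws, y + 0.5, n - y + 0.5)
    } else {
      stats::rbeta(n_draws, y, n - y)
    }
  })
  names(post) <- names(cells)
  prob <- mean((post$p1a - post$p0a) - (post$p1b - post$p0b) > 0)
  method_result("cutoff", prob, threshold, direction = "reject_above",
                diagnostics = list(selected_cutoff = c_star,
                                   cells = lapply(cells, as.list),
                                   jeffreys_fallback = jeffreys))
}

## empirical AUC (higher biomarker => predicted responder) and DeLong
## structural-component variance for one arm; ties count one half
auc_components <- function(x_cases, x_controls) {
  m <- length(x_cases); n <- length(x_controls)
  cmp <- outer(x_cases, x_controls, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(cmp)   # placement of each case among controls
  v01 <- colMeans(cmp)   # placement of each control among cases
  auc <- mean(cmp)
  var_auc <- if (m > 1 && n > 1)
    stats::var(v10) / m + stats::var(v01) / n
  else 0
  list(auc = auc, var = var_auc, m = m, n = n)
}

#' DeLong test comparing the per-arm ROC areas
#'
#' Builds the empirical ROC of biomarker against response within each
#' arm (higher biomarker predicts response; ties counted one half, so
#' the AUC equals the Mann-Whitney two-sample statistic), estimates each
#' AUC's variance via DeLong structural components, and reports the
#' one-sided p-value for `H0: AUC1 - AUC0 <= 0` (the two arms are
#' independent samples).  The reference distribution is Student's t with
#' Welch-Satterthwaite degrees of freedom, as in the `pROC`
#' implementation of the unpaired DeLong test.  An arm lacking
#' responders or non-responders gives the no-evidence metric 1, flagged.
#'
#' @param data a [trial_data()].
#' @param threshold decision threshold `alpha_DeLong`.
#' @return a [method_result()]; diagnostics carry both AUCs.
#' @export
delong_test <- function(data, threshold = default_thresholds()[["delong"]]) {
  comp <- lapply(c(0, 1), function(k) {
    y <- data$response[data$arm == k]
    x <- data$biomarker[data$arm == k]
    if (sum(y == 1) == 0 || sum(y == 0) == 0) return(NULL)
    auc_components(x[y == 1], x[y == 0])
  })
  if (any(vapply(comp, is.null, logical(1))))
    return(method_result("delong", 1, threshold,
                         diagnostics = list(reason = "arm without both outcome classes"),
                         flagged = TRUE))
  a0 <- comp[[1]]; a1 <- comp[[2]]
  diff <- a1$auc - a0$auc
  v <- a1$var + a0$var
  if (v <= 0) {
    p <- as.numeric(diff <= 0)
  } else {
    df <- v^2 / (a1$var^2 / (a1$m + a1$n - 1) + a0$var^2 / (a0$m + a0$n - 1))
    p <- stats::pt(diff / sqrt(v), df = df, lower.tail = FALSE)
  }
  method_result("delong", p, threshold,
                diagnostics = list(auc1 = a1$auc, auc0 = a0$auc,
                                   variance = v))
}

#' Apply every method to one trial dataset
#'
#' Runs AKSA and the six comparators with shared defaults and returns a
#' named list of [method_result()] objects.
#'
#' @param data a [trial_data()].
#' @param methods subset of
#'   `c("it", "itd", "lr", "stepp", "cutoff", "delong", "aksa")` or
#'   `"all"`.
#' @param thresholds named threshold vector (see [default_thresholds()]).
#' @param B AKSA couples.
#' @param n_perm STEPP permutations.
#' @param n_draws cutoff posterior draws.
#' @param r1,r2 STEPP window parameters.
#' @param seed optional integer seed (shared by the stochastic methods).
#' @return named list of [method_result()].
#' @export
analyze_trial <- function(data, methods = "all",
                          thresholds = default_thresholds(),
                          B = 10000, n_perm = 1000, n_draws = 10000,
                          r1 = 15, r2 = 40, seed = NULL) {
  all_m <- c("it", "itd", "lr", "stepp", "cutoff", "delong", "aksa")
  if (identical(methods, "all")) methods <- all_m
  stopifnot(all(methods %in% all_m))
  maybe_seed(seed)
  out <- list()
  for (m in methods) {
    out[[m]] <- switch(m,
      it = interaction_test(data, thresholds[["it"]]),
      itd = interaction_test_dichotomised(data, threshold = thresholds[["itd"]]),
      lr = likelihood_ratio_test(data, thresholds[["lr"]]),
      stepp = stepp_test(data, r1 = r1, r2 = r2, n_perm = n_perm,
                         threshold = thresholds[["stepp"]]),
      cutoff = cutoff_probability(data, n_draws = n_draws,
                                  threshold = thresholds[["cutoff"]]),
      delong = delong_test(data, thresholds[["delong"]]),
      aksa = aksa_test(data, B = B, alpha_aksa = thresholds[["aksa"]])
    )
  }
  out
}
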