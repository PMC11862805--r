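#' Threshold calibration at a common type-I error level
#'
#' Each method's decision threshold is chosen by simulation so that the
#' worst-case rejection rate over all null scenario x biomarker
#' distribution cells is at most `alpha` (15% by default):
#' [collect_null_metrics()] simulates trials under the null cells and
#' stores every method's metric; [calibrate_threshold()] scans a grid of
#' candidate thresholds and keeps the least conservative feasible one.
#'
#' @name calibration
NULL

## one replicate's metrics for the requested methods, sharing the
## interaction fit between IT, LR and AKSA
compute_metrics <- function(data, methods, B = 2000, n_perm = 500,
                            n_draws = 2000, r1 = 15, r2 = 40) {
  out <- stats::setNames(rep(NA_real_, length(methods)), methods)
  fit <- nested <- NULL
  if (any(c("it", "lr", "aksa") %in% methods))
    fit <- tryCatch(fit_logistic_interaction(data), error = function(e) NULL)
  for (m in methods) {
    out[m] <- tryCatch(switch(m,
      it = if (is.null(fit)) 1 else interaction_pvalue(fit),
      lr = {
        if (is.null(fit) || fit$separated || fit$rank_deficient) 1
        else {
          nested <- nested %||% fit_logistic_main(data)
          if (nested$separated) 1
          else stats::pchisq(max(0, 2 * (fit$loglik - nested$loglik)),
                             df = 1, lower.tail = FALSE)
        }
      },
      aksa = {
        if (is.null(fit)) 0.5
        else aksa_probability(fit, sample_couples(data$biomarker, B))$probability
      },
      itd = interaction_test_dichotomised(data)$metric,
      cutoff = cutoff_probability(data, n_draws = n_draws)$metric,
      delong = delong_test(data)$metric,
      stepp = stepp_test(data, r1 = r1, r2 = r2, n_perm = n_perm)$metric
    ), error = function(e) if (m %in% c("aksa", "cutoff")) 0.5 else 1)
  }
  out
}

#' Collect method metrics under null scenarios
#'
#' For every null cell (scenario x distribution) simulates `n_reps`
#' trials and records each requested method's metric.  All methods see
#' the same simulated dataset within a replicate (common random
#' numbers).  `n_reps` may be a named per-method vector; the dataset
#' stream is generated at the maximum and method `m` is evaluated on the
#' first `n_reps[m]` replicates.
#'
#' @param specs named list of null [scenario_spec()]s (see
#'   [preset_scenarios()] restricted to [null_labels()]).
#' @param methods character vector of method names.
#' @param n_reps replications per cell (scalar or named per-method).
#' @param seed master seed.
#' @param B,n_perm,n_draws,r1,r2 method tuning parameters.
#' @return data.frame with columns `cell`, `method`, `rep`, `metric`.
#' @export
collect_null_metrics <- function(specs, methods, n_reps, seed = 1,
                                 B = 2000, n_perm = 500, n_draws = 2000,
                                 r1 = 15, r2 = 40) {
  if (is.null(names(n_reps)))
    n_reps <- stats::setNames(rep(n_reps[1], length(methods)), methods)
  stopifnot(all(methods %in% names(n_reps)))
  max_reps <- max(n_reps[methods])
  cell_seeds <- derive_seeds(seed, length(specs))
  res <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    coeffs <- solve_coefficients(spec)
    rep_seeds <- derive_seeds(cell_seeds[i], max_reps)
    mat <- matrix(NA_real_, nrow = max_reps, ncol = length(methods),
                  dimnames = list(NULL, methods))
    for (r in seq_len(max_reps)) {
      set.seed(rep_seeds[r])
      dat <- simulate_trial(coeffs, spec)
      m_here <- methods[n_reps[methods] >= r]
      mat[r, m_here] <- compute_metrics(dat, m_here, B = B, n_perm = n_perm,
                                        n_draws = n_draws, r1 = r1, r2 = r2)
    }
    long <- data.frame(cell = names(specs)[i],
                       method = rep(methods, each = max_reps),
                       rep = rep(seq_len(max_reps), length(methods)),
                       metric = as.numeric(mat))
    res[[i]] <- long[!is.na(long$metric), ]
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Calibrate one decision threshold from null metric samples
#'
#' For a p-value method (`reject_below`) the threshold is the largest
#' grid value `t` such that the worst-case fraction of samples with
#' `metric < t` over all cells is at most `alpha`; for a probability
#' method (`reject_above`) it is the smallest `t` such that the
#' worst-case fraction with `metric > t` is at most `alpha`.
#'
#' @param samples list of numeric metric vectors, one per null cell.
#' @param direction `"reject_below"` or `"reject_above"`.
#' @param alpha type-I error target.
#' @param grid_step grid resolution (0.01 default; 0.001 recommended for
#'   the cutoff probability).
#' @return scalar threshold.
#' @export
calibrate_threshold <- function(samples, direction = c("reject_below", "reject_above"),
                                alpha = 0.15, grid_step = 0.01) {
  direction <- match.arg(direction)
  if (!is.list(samples)) samples <- list(samples)
  stopifnot(all(lengths(samples) > 0))
  if (direction == "reject_below") {
    grid <- seq(grid_step, 1 - grid_step, by = grid_step)
    worst <- vapply(grid, function(t)
      max(vapply(samples, function(s) mean(s < t), numeric(1))), numeric(1))
    ok <- worst <= alpha
    if (!any(ok)) {
      warning("no feasible threshold; returning the smallest grid value")
      return(grid[1])
    }
    grid[max(which(ok))]
  } else {
    grid <- seq(grid_step, 1 - grid_step, by = grid_step)
    worst <- vapply(grid, function(t)
      max(vapply(samples, function(s) mean(s > t), numeric(1))), numeric(1))
    ok <- worst <= alpha
    if (!any(ok)) {
      warning("no feasible threshold; returning the largest grid value")
      return(grid[length(grid)])
    }
    grid[min(which(ok))]
  }
}

#' Calibrate all thresholds from a collected metric table
#'
#' @param metrics data.frame from [collect_null_metrics()].
#' @param alpha type-I error target.
#' @param grid_steps named per-method grid resolutions; unnamed methods
#'   use 0.01 (the cutoff probability defaults to 0.001).
#' @return data.frame with columns `method`, `direction`, `threshold`,
#'   `worst_null_rejection`.
#' @export
calibrate_thresholds <- function(metrics, alpha = 0.15,
                                 grid_steps = c(cutoff = 0.001)) {
  methods <- unique(metrics$method)
  rows <- lapply(methods, function(m) {
    sub <- metrics[metrics$method == m, ]
    samples <- split(sub$metric, sub$cell)
    dir <- method_direction(m)
    step <- if (m %in% names(grid_steps)) grid_steps[[m]] else 0.01
    thr <- calibrate_threshold(samples, dir, alpha, step)
    worst <- max(vapply(samples, function(s)
      if (dir == "reject_below") mean(s < thr) else mean(s > thr), numeric(1)))
    data.frame(method = m, direction = dir, threshold = thr,
               worst_null_rejection = worst, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
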