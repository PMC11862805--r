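#' STEPP sliding-window heterogeneity test
#'
#' The subpopulation treatment effect pattern plot (STEPP) divides the
#' biomarker-sorted population into overlapping subgroups of `r2`
#' patients with at most `r1` patients shared between consecutive
#' subgroups, estimates the arm difference in response rates within each
#' subgroup, and tests the global null of a common treatment effect with
#' the maximum standardized deviation from the overall effect,
#' `S = max_j |theta_j - theta_ALL| / sigma_j`, calibrated by permuting
#' the treatment labels.
#'
#' @name stepp
NULL

#' Build overlapping biomarker-ordered windows
#'
#' Patients are sorted by biomarker (ties broken by original order);
#' windows of `r2` consecutive ranks advance by `r2 - r1`, and the final
#' window is truncated at the last patient (so it may be smaller).  With
#' `n = 60`, `r1 = 15`, `r2 = 40` this gives ranks 1-40 and 26-60.
#'
#' @param data a [trial_data()].
#' @param r1 maximum overlap between consecutive windows.
#' @param r2 patients per window.
#' @return object of class `stepp_windows` with the sort order and a
#'   logical membership matrix (windows x patients, original order).
#' @export
stepp_windows <- function(data, r1 = 15, r2 = 40) {
  n <- nrow(data)
  stopifnot(r1 >= 0, r2 >= 1, r1 < r2)
  flagged <- FALSE
  if (r2 > n) {
    r2 <- n
    flagged <- TRUE
  }
  ord <- order(data$biomarker)          # stable: ties keep input order
  step <- r2 - r1
  starts <- 1L
  while (utils::tail(starts, 1) + r2 - 1L < n)
    starts <- c(starts, utils::tail(starts, 1) + step)
  membership <- matrix(FALSE, nrow = length(starts), ncol = n)
  for (j in seq_along(starts)) {
    ranks <- starts[j]:min(starts[j] + r2 - 1L, n)
    membership[j, ord[ranks]] <- TRUE
  }
  structure(list(order = ord, starts = starts, r1 = r1, r2 = r2,
                 membership = membership, flagged = flagged),
            class = "stepp_windows")
}

#' @export
print.stepp_windows <- function(x, ...) {
  cat(sprintf("STEPP windows: %d windows (r1=%d, r2=%d) over %d patients\n",
              nrow(x$membership), x$r1, x$r2, ncol(x$membership)))
  for (j in seq_along(x$starts)) {
    last <- min(x$starts[j] + x$r2 - 1L, ncol(x$membership))
    cat(sprintf("  window %d: sorted ranks %d-%d\n", j, x$starts[j], last))
  }
  invisible(x)
}

## per-window and overall arm-difference estimates for a given label
## vector; windows lacking an arm are dropped (NA row).  Vectorised over
## columns of `arms` so permutations cost two matrix products.
stepp_stat_matrix <- function(membership, arms, response) {
  W <- membership * 1                                  # J x n
  A <- as.matrix(arms)                                 # n x P
  Ay <- A * response
  n1 <- W %*% A;  y1 <- W %*% Ay                       # J x P
  n0 <- W %*% (1 - A); y0 <- W %*% ((1 - A) * response)
  p1 <- y1 / n1; p0 <- y0 / n0
  theta <- p1 - p0
  N1 <- colSums(A); N0 <- colSums(1 - A)
  P1 <- colSums(Ay) / N1; P0 <- colSums((1 - A) * response) / N0
  theta_all <- P1 - P0
  v_all <- P1 * (1 - P1) / N1 + P0 * (1 - P0) / N0
  v_j <- p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0
  ## nested-variance standardization with positivity floor
  sigma2 <- pmax(sweep(v_j, 2, v_all, "-"), v_j * 1e-3)
  dev <- abs(sweep(theta, 2, theta_all, "-")) / sqrt(sigma2)
  dev[n1 == 0 | n0 == 0] <- NA                         # window lacking an arm
  ## column maxima over the few windows without per-column R calls
  S <- dev[1, ]
  for (j in seq_len(nrow(dev))[-1]) S <- pmax(S, dev[j, ], na.rm = TRUE)
  S[!is.finite(S)] <- NA                               # no valid window
  list(S = S, theta = theta, theta_all = theta_all, sigma2 = sigma2)
}

#' Observed STEPP statistic
#'
#' `S = max_j |theta_j - theta_ALL| / sigma_j` with `theta_j` the
#' within-window difference of response proportions and `sigma_j` the
#' nested plug-in variance estimate (window variance minus full-sample
#' variance, floored at one thousandth of the window variance for
#' positivity).  Windows lacking an arm are dropped.
#'
#' @param windows a [stepp_windows()] object.
#' @param data the matching [trial_data()].
#' @return list with `S`, per-window `theta`, `sigma`, and `theta_all`.
#' @export
stepp_statistic <- function(windows, data) {
  res <- stepp_stat_matrix(windows$membership, data$arm, data$response)
  if (is.na(res$S[1])) stop("no window contains both arms")
  list(S = res$S[1], theta = as.numeric(res$theta[, 1]),
       sigma = as.numeric(sqrt(res$sigma2[, 1])),
       theta_all = res$theta_all[1])
}

#' STEPP permutation test
#'
#' Recomputes the statistic under `n_perm` random permutations of the
#' treatment labels (biomarker/response pairs fixed) and reports the
#' add-one p-value `(1 + #{S_perm >= S_obs}) / (1 + n_perm)`.
#' Permutations in which no window retains both arms are redrawn
#' (bounded retries).
#'
#' @param data a [trial_data()].
#' @param r1,r2 window parameters (defaults 15 and 40; use `r2 = 20` for
#'   30-patient trials).
#' @param n_perm number of permutations.
#' @param threshold decision threshold `alpha_STEPP`.
#' @param seed optional integer seed.
#' @return a [method_result()]; diagnostics carry `S_obs` and the
#'   per-window effects.
#' @export
stepp_test <- function(data, r1 = 15, r2 = 40, n_perm = 1000,
                       threshold = default_thresholds()[["stepp"]],
                       seed = NULL) {
  stopifnot(n_perm >= 1)
  win <- stepp_windows(data, r1, r2)
  obs <- tryCatch(stepp_statistic(win, data), error = function(e) NULL)
  if (is.null(obs))
    return(method_result("stepp", 1, threshold,
                         diagnostics = list(reason = "no valid window"),
                         flagged = TRUE))
  maybe_seed(seed)
  n <- nrow(data)
  ## label permutations in bulk: one radix order call on random keys
  ## gives n_perm independent permutations of the arm vector
  g <- rep.int(seq_len(n_perm), rep.int(n, n_perm))
  o <- order(g, stats::runif(n * n_perm))
  perms <- matrix(data$arm[(o - 1L) %% n + 1L], nrow = n)
  S_perm <- stepp_stat_matrix(win$membership, perms, data$response)$S
  bad <- which(is.na(S_perm))
  retries <- 0
  while (length(bad) && retries < 100) {
    redraw <- vapply(bad, function(i) sample(data$arm), integer(n))
    S_perm[bad] <- stepp_stat_matrix(win$membership, redraw, data$response)$S
    bad <- which(is.na(S_perm))
    retries <- retries + 1
  }
  S_perm <- S_perm[!is.na(S_perm)]
  p <- (1 + sum(S_perm >= obs$S)) / (1 + length(S_perm))
  method_result("stepp", p, threshold,
                diagnostics = list(S_obs = obs$S, n_windows = length(obs$theta),
                                   theta = obs$theta, theta_all = obs$theta_all,
                                   n_perm = length(S_perm)),
                flagged = win$flagged)
}
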