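#' Operating-characteristics study
#'
#' Reproduces the simulation study design: for each scenario x
#' distribution cell, trials are simulated, every method is applied to
#' the same dataset with its calibrated threshold, and the rejection rate
#' (type-I error under nulls, power under alternatives) is tabulated with
#' its Monte-Carlo standard error.
#'
#' @name operating_characteristics
NULL

#' Run the rejection-rate study over a scenario grid
#'
#' @param specs named list of [scenario_spec()]s (see
#'   [preset_scenarios()]).
#' @param thresholds named threshold vector (e.g. [default_thresholds()]
#'   or the `threshold` column of [calibrate_thresholds()]).
#' @param methods method names to run.
#' @param n_reps replications per cell (scalar or named per-method).
#' @param seed master seed.
#' @param B,n_perm,n_draws,r1,r2 method tuning parameters.
#' @return data.frame with columns `scenario`, `dist`, `method`,
#'   `n_reps`, `rejection_rate`, `mc_se`.
#' @export
run_study <- function(specs, thresholds = default_thresholds(),
                      methods = names(default_thresholds()),
                      n_reps = 1000, seed = 1, B = 2000, n_perm = 500,
                      n_draws = 2000, r1 = 15, r2 = 40) {
  stopifnot(all(methods %in% names(thresholds)))
  if (is.null(names(n_reps)))
    n_reps <- stats::setNames(rep(n_reps[1], length(methods)), methods)
  max_reps <- max(n_reps[methods])
  cell_seeds <- derive_seeds(seed, length(specs))
  rows <- vector("list", length(specs))
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
    rates <- vapply(methods, function(m) {
      v <- mat[seq_len(n_reps[[m]]), m]
      dir <- method_direction(m)
      mean(if (dir == "reject_below") v < thresholds[[m]] else v > thresholds[[m]])
    }, numeric(1))
    rows[[i]] <- data.frame(
      scenario = spec$label, dist = spec$dist$label, method = methods,
      n_reps = as.integer(n_reps[methods]), rejection_rate = unname(rates),
      mc_se = sqrt(unname(rates) * (1 - unname(rates)) / n_reps[methods]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity-analysis study presets
#'
#' Named configurations varying the sample size, truth form and
#' experimental response rate: the base 40:20 trial; balanced 40:40;
#' balanced 100-patient (50:50); a small 30-patient trial (20:10, with
#' the STEPP window size reduced to 20 and thresholds to be
#' re-calibrated); step-function truth; experimental ORR 50%.
#'
#' @return named list of configuration lists with elements `n1`, `n0`,
#'   `r1`, `r2`, `truth_form`, `experimental_orr`, `recalibrate`.
#' @export
sensitivity_presets <- function() {
  base <- list(n1 = 40L, n0 = 20L, r1 = 15L, r2 = 40L,
               truth_form = "logistic", experimental_orr = 0.6,
               recalibrate = FALSE)
  mod <- function(...) utils::modifyList(base, list(...))
  list(
    base        = base,
    balanced40  = mod(n1 = 40L, n0 = 40L),
    balanced100 = mod(n1 = 50L, n0 = 50L),
    small       = mod(n1 = 20L, n0 = 10L, r2 = 20L, recalibrate = TRUE),
    step        = mod(truth_form = "step"),
    orr50       = mod(experimental_orr = 0.5)
  )
}

#' Summarise a rejection-rate table
#'
#' Rejection rates are grouped into type-I error (null scenarios) and
#' power (alternatives, by prognostic stratum parsed from the label);
#' the per-method minimum and maximum within each stratum is reported.
#'
#' @param table output of [run_study()].
#' @return data.frame with columns `method`, `stratum`, `min_rate`,
#'   `max_rate`, `n_cells`.
#' @export
summarize_study <- function(table) {
  stopifnot(nrow(table) > 0)
  is_null <- table$scenario %in% null_labels()
  stratum <- ifelse(is_null, "type1",
                    paste0("power_prognostic_", substr(table$scenario, 3, 3)))
  key <- paste(table$method, stratum)
  rows <- lapply(split(seq_len(nrow(table)), key), function(idx) {
    data.frame(method = table$method[idx[1]], stratum = stratum[idx[1]],
               min_rate = min(table$rejection_rate[idx]),
               max_rate = max(table$rejection_rate[idx]),
               n_cells = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$method, out$stratum), ]
}
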