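#' Simulation scenario specification
#'
#' A scenario fixes the data-generating truth for one simulated trial
#' setting: the functional form of the arm response curves (logistic or
#' step), the target marginal response rates, the predictive effect (the
#' difference of arm-differences in response rate above vs below the true
#' cutoff), the prognostic effect, the biomarker distribution and the arm
#' sizes.  [solve_coefficients()] turns the targets into concrete
#' outcome-model parameters; [simulate_trial()] draws datasets from them.
#'
#' The prognostic effect is encoded two ways, matching how the scenario
#' families are built: for alternative scenarios it is a fraction
#' `prognostic_fraction` (kappa) of the predictive effect, implemented on
#' the logit scale as `b3 = kappa * b2`; for the prognostic null
#' scenarios (no interaction, `b2 = 0`) it is an absolute magnitude
#' `prognostic_magnitude` on the response-probability scale at a fixed
#' cutoff (default 17).
#'
#' @param label scenario code, e.g. `"NPNPT"` or `"HPNP_50"`.
#' @param dist a [biomarker_dist()].
#' @param control_orr,experimental_orr target marginal response rates.
#' @param predictive_effect target predictive effect in `[0, 1]`.
#' @param prognostic_fraction kappa in `{0, 0.2, 0.5}`.
#' @param prognostic_magnitude absolute prognostic effect for the
#'   prognostic null scenarios (response-probability scale).
#' @param fixed_cutoff cutoff used when the truth has no curve
#'   intersection (prognostic nulls, step truth).
#' @param truth_form `"logistic"` or `"step"`.
#' @param n1,n0 arm sizes (experimental, control).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(label, dist, control_orr, experimental_orr,
                          predictive_effect = 0, prognostic_fraction = 0,
                          prognostic_magnitude = 0, fixed_cutoff = NULL,
                          truth_form = c("logistic", "step"),
                          n1 = 40, n0 = 20) {
  truth_form <- match.arg(truth_form)
  stopifnot(inherits(dist, "biomarker_dist"),
            control_orr > 0, control_orr < 1,
            experimental_orr > 0, experimental_orr < 1,
            predictive_effect >= 0, predictive_effect <= 1,
            prognostic_fraction >= 0, n1 >= 1, n0 >= 1)
  structure(list(label = label, dist = dist,
                 control_orr = control_orr,
                 experimental_orr = experimental_orr,
                 predictive_effect = predictive_effect,
                 prognostic_fraction = prognostic_fraction,
                 prognostic_magnitude = prognostic_magnitude,
                 fixed_cutoff = fixed_cutoff, truth_form = truth_form,
                 n1 = as.integer(n1), n0 = as.integer(n0)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %s (%s truth, %s biomarker): ORR %g%%/%g%% (exp/ctrl), predictive %g, kappa %g, n %d:%d\n",
              x$label, x$truth_form, x$dist$label,
              100 * x$experimental_orr, 100 * x$control_orr,
              x$predictive_effect, x$prognostic_fraction, x$n1, x$n0))
  invisible(x)
}

new_scenario_coefficients <- function(b0, b1, b2, b3, true_cutoff = NULL,
                                      truth_form = "logistic",
                                      step_params = NULL) {
  structure(list(b0 = b0, b1 = b1, b2 = b2, b3 = b3,
                 true_cutoff = true_cutoff, truth_form = truth_form,
                 step_params = step_params),
            class = "scenario_coefficients")
}

#' @export
print.scenario_coefficients <- function(x, ...) {
  if (x$truth_form == "logistic") {
    cat(sprintf("Logistic truth: b0=%.4f b1=%.4f b2=%.5f b3=%.5f cutoff=%s\n",
                x$b0, x$b1, x$b2, x$b3,
                if (is.null(x$true_cutoff)) "none" else sprintf("%.3f", x$true_cutoff)))
  } else {
    sp <- x$step_params
    cat(sprintf("Step truth at cutoff %.3f: control %.3f/%.3f, experimental %.3f/%.3f (below/above)\n",
                sp$cutoff, sp$p0_below, sp$p0_above, sp$p1_below, sp$p1_above))
  }
  invisible(x)
}

## arm response probability under the truth, vectorised over x
truth_prob <- function(coeffs, arm, x) {
  if (coeffs$truth_form == "step") {
    sp <- coeffs$step_params
    below <- x <= sp$cutoff
    if (arm == 1) ifelse(below, sp$p1_below, sp$p1_above)
    else          ifelse(below, sp$p0_below, sp$p0_above)
  } else {
    stats::plogis(coeffs$b0 + coeffs$b1 * arm + coeffs$b2 * x * arm + coeffs$b3 * x)
  }
}

## E[ f(X) ] restricted to (lower, upper), unnormalised, by adaptive quadrature
quad_int <- function(f, dist, lower, upper) {
  if (upper <= lower) return(0)
  stats::integrate(function(x) f(x) * bm_density(dist, x), lower, upper,
                   rel.tol = 1e-10, abs.tol = 1e-10,
                   subdivisions = 500L)$value
}

#' Marginal overall response rate of one arm
#'
#' `E_X[p_arm(X)]` over the biomarker distribution, by adaptive
#' quadrature on the distribution's central `1 - 2e-8` probability range
#' (absolute tolerance below 1e-6), or the exact two-cell average for a
#' step truth.
#'
#' @param coeffs a `scenario_coefficients` object.
#' @param arm 0 or 1.
#' @param dist a [biomarker_dist()] (gamma or uniform).
#' @return scalar probability.
#' @export
marginal_orr <- function(coeffs, arm, dist) {
  stopifnot(arm %in% c(0, 1))
  if (coeffs$truth_form == "step") {
    sp <- coeffs$step_params
    q <- bm_cdf(dist, sp$cutoff)
    pb <- if (arm == 1) sp$p1_below else sp$p0_below
    pa <- if (arm == 1) sp$p1_above else sp$p0_above
    return(q * pb + (1 - q) * pa)
  }
  if (dist$family == "empirical")
    return(mean(truth_prob(coeffs, arm, dist$values)))
  sup <- bm_support(dist)
  quad_int(function(x) truth_prob(coeffs, arm, x), dist, sup[1], sup[2])
}

#' Predictive and prognostic effects implied by a truth at a cutoff
#'
#' The predictive effect is the difference of arm differences in mean
#' response rate above vs below the cutoff,
#' `(E[p1 - p0 | X > c]) - (E[p1 - p0 | X <= c])`; the prognostic effect
#' is the within-control difference `E[p0 | X > c] - E[p0 | X <= c]`.
#' Conditional expectations are computed by quadrature.
#'
#' @inheritParams marginal_orr
#' @param cutoff cutoff with non-zero probability mass on both sides.
#' @return list with elements `predictive` and `prognostic`.
#' @export
predictive_prognostic_effects <- function(coeffs, dist, cutoff) {
  q <- bm_cdf(dist, cutoff)
  if (q <= 0 || q >= 1) stop("cutoff leaves zero mass on one side")
  cond_mean <- function(arm, side) {
    if (coeffs$truth_form == "step") {
      sp <- coeffs$step_params
      # constant within each side when the truth cutoff equals the query
      # cutoff; otherwise integrate the piecewise curve
      if (isTRUE(all.equal(cutoff, sp$cutoff)))
        return(if (arm == 1) {
          if (side == "below") sp$p1_below else sp$p1_above
        } else {
          if (side == "below") sp$p0_below else sp$p0_above
        })
    }
    sup <- bm_support(dist)
    if (side == "below")
      quad_int(function(x) truth_prob(coeffs, arm, x), dist, sup[1], cutoff) / q
    else
      quad_int(function(x) truth_prob(coeffs, arm, x), dist, cutoff, sup[2]) / (1 - q)
  }
  p1a <- cond_mean(1, "above"); p1b <- cond_mean(1, "below")
  p0a <- cond_mean(0, "above"); p0b <- cond_mean(0, "below")
  list(predictive = (p1a - p0a) - (p1b - p0b), prognostic = p0a - p0b)
}

## damped Newton with numerical Jacobian and seeded random restarts
newton_solve <- function(res_fn, start, max_iter = 200, tol = 1e-8,
                         n_restarts = 8, seed = 1) {
  safe_res <- function(par) {
    r <- tryCatch(res_fn(par), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) rep(1e6, length(start)) else r
  }
  run_from <- function(par) {
    for (iter in seq_len(max_iter)) {
      r <- safe_res(par)
      nr <- sqrt(sum(r^2))
      if (nr < tol) return(list(par = par, residual = nr, converged = TRUE))
      h <- pmax(abs(par), 1) * 1e-7
      J <- vapply(seq_along(par), function(j) {
        pj <- par; pj[j] <- pj[j] + h[j]
        (safe_res(pj) - r) / h[j]
      }, numeric(length(r)))
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step)) return(list(par = par, residual = nr, converged = FALSE))
      lambda <- 1
      repeat {
        cand <- par + lambda * step
        if (sqrt(sum(safe_res(cand)^2)) < nr || lambda < 1e-6) break
        lambda <- lambda / 2
      }
      par <- par + lambda * step
    }
    r <- safe_res(par)
    list(par = par, residual = sqrt(sum(r^2)), converged = sqrt(sum(r^2)) < tol)
  }
  best <- run_from(start)
  if (!best$converged) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    set.seed(as.integer(seed))
    for (k in seq_len(n_restarts)) {
      cand <- run_from(start * stats::runif(length(start), 0.5, 1.5) +
                         stats::rnorm(length(start), 0, 0.2))
      if (cand$residual < best$residual) best <- cand
      if (best$converged) break
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  best
}

#' Solve outcome-model coefficients from scenario targets
#'
#' For a logistic truth, finds `(b0, b1, b2, b3)` of
#' `logit p = b0 + b1*T + b2*X*T + b3*X` such that (i) the marginal
#' control ORR matches `control_orr`, (ii) the marginal experimental ORR
#' matches `experimental_orr`, (iii) the predictive effect evaluated at
#' the true cutoff matches `predictive_effect`, and (iv)
#' `b3 = prognostic_fraction * b2`.  For alternative scenarios the cutoff
#' is the self-consistent curve intersection `-b1/b2`; for prognostic
#' null scenarios (`b2 = 0`) the cutoff is `fixed_cutoff` and the
#' predictive constraint is replaced by a prognostic-magnitude
#' constraint.  Solved by damped Newton iteration with seeded random
#' restarts (tolerance 1e-8 on the residuals, matching the accuracy of
#' the forward-difference Jacobian over the quadrature).
#'
#' For a step truth the four cell probabilities (per arm, below/above the
#' scenario cutoff) solve the same ORR / predictive / prognostic
#' constraints in closed form.
#'
#' @param spec a [scenario_spec()].
#' @return object of class `scenario_coefficients`.
#' @export
solve_coefficients <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  dist <- spec$dist
  co <- spec$control_orr; eo <- spec$experimental_orr
  delta <- spec$predictive_effect; kappa <- spec$prognostic_fraction

  if (spec$truth_form == "step") return(solve_step_coefficients(spec))

  prognostic_null <- delta == 0 && spec$prognostic_magnitude > 0
  if (delta == 0 && !prognostic_null) {
    ## flat curves: closed form
    return(new_scenario_coefficients(
      b0 = stats::qlogis(co), b1 = stats::qlogis(eo) - stats::qlogis(co),
      b2 = 0, b3 = 0, true_cutoff = NULL))
  }

  if (prognostic_null) {
    cutoff <- spec$fixed_cutoff %||% 17
    res_fn <- function(par) {  # par = (b0, b3, b1), b2 = 0
      cf <- new_scenario_coefficients(par[1], par[3], 0, par[2])
      eff <- predictive_prognostic_effects(cf, dist, cutoff)
      c(marginal_orr(cf, 0, dist) - co,
        eff$prognostic - spec$prognostic_magnitude,
        marginal_orr(cf, 1, dist) - eo)
    }
    sol <- newton_solve(res_fn, c(stats::qlogis(co), 0.02,
                                  stats::qlogis(eo) - stats::qlogis(co)))
    if (!sol$converged)
      stop(sprintf("coefficient solve failed for %s (residual %.2e)",
                   spec$label, sol$residual))
    return(new_scenario_coefficients(sol$par[1], sol$par[3], 0, sol$par[2],
                                     true_cutoff = cutoff))
  }

  ## With an interior intersection the predictive effect strictly
  ## exceeds the marginal treatment effect (the above-cutoff arm
  ## difference exceeds the marginal difference while the below-cutoff
  ## one is negative).  A target equal to the marginal effect is only
  ## attained in the boundary limit where the intersection sits at the
  ## bottom of the biomarker support; smaller targets are unattainable.
  trt_eff <- eo - co
  if (delta < trt_eff - 1e-9)
    stop(sprintf(
      "predictive effect %.3f below the marginal treatment effect %.3f is unattainable",
      delta, trt_eff))
  if (delta <= trt_eff + 1e-9) {
    cutoff <- bm_quantile(dist, 1e-4)
    res_fn0 <- function(par) {  # par = (b0, b2), b1 = -b2 * cutoff
      if (par[2] <= 1e-8) return(rep(1e6, 2))
      cf <- new_scenario_coefficients(par[1], -par[2] * cutoff, par[2],
                                      kappa * par[2])
      c(marginal_orr(cf, 0, dist) - co, marginal_orr(cf, 1, dist) - eo)
    }
    sol <- newton_solve(res_fn0, c(stats::qlogis(co), 0.03))
    if (!sol$converged)
      stop(sprintf("coefficient solve failed for %s (residual %.2e)",
                   spec$label, sol$residual))
    b2 <- sol$par[2]
    cf <- new_scenario_coefficients(sol$par[1], -b2 * cutoff, b2,
                                    kappa * b2, true_cutoff = cutoff)
    cf$realized_predictive <-
      predictive_prognostic_effects(cf, dist, cutoff)$predictive
    return(cf)
  }

  ## non-prognostic alternative: par = (b0, b1, b2), b3 = 0, cutoff =
  ## -b1/b2 (curve intersection), solved self-consistently so that the
  ## predictive effect at the cutoff equals the target exactly
  ## the cutoff must be interior (1%-99% quantile box) so that the
  ## conditional expectations on both sides carry real probability mass;
  ## without the box the system admits degenerate boundary roots
  box <- c(bm_quantile(dist, 0.01), bm_quantile(dist, 0.99))
  mid <- bm_quantile(dist, 0.5)
  res_fn <- function(par) {
    b0 <- par[1]; b1 <- par[2]; b2 <- par[3]
    if (b2 <= 1e-8) return(rep(1e6, 3))
    cutoff <- -b1 / b2
    if (cutoff <= box[1] || cutoff >= box[2]) return(rep(1e6, 3))
    cf <- new_scenario_coefficients(b0, b1, b2, 0)
    eff <- predictive_prognostic_effects(cf, dist, cutoff)
    c(marginal_orr(cf, 0, dist) - co,
      marginal_orr(cf, 1, dist) - eo,
      eff$predictive - delta)
  }
  start <- c(stats::qlogis(co), -0.08 * mid, 0.08)
  sol <- newton_solve(res_fn, start)
  if (!sol$converged)
    stop(sprintf("coefficient solve failed for %s (residual %.2e)",
                 spec$label, sol$residual))
  b0 <- sol$par[1]; b1 <- sol$par[2]; b2 <- sol$par[3]
  if (kappa == 0)
    return(new_scenario_coefficients(b0, b1, b2, 0, true_cutoff = -b1 / b2))

  ## prognostic variant: carry the interaction slope b2 over from the
  ## non-prognostic base, set b3 = kappa * b2, and re-solve (b0, b1) for
  ## the two marginal ORR constraints.  The full constraint set (exact
  ## nominal predictive effect AND b3 = kappa*b2 AND both ORRs) is
  ## jointly infeasible on the probability scale for the larger effect
  ## sizes, so the nominal effect is attached to the base slope and the
  ## realized effect is recorded on the result.
  res_fn2 <- function(par) {
    cf <- new_scenario_coefficients(par[1], par[2], b2, kappa * b2)
    c(marginal_orr(cf, 0, dist) - co,
      marginal_orr(cf, 1, dist) - eo)
  }
  sol2 <- newton_solve(res_fn2, c(b0, b1))
  if (!sol2$converged)
    stop(sprintf("coefficient solve failed for %s (residual %.2e)",
                 spec$label, sol2$residual))
  cutoff <- -sol2$par[2] / b2
  cf <- new_scenario_coefficients(sol2$par[1], sol2$par[2], b2, kappa * b2,
                                  true_cutoff = cutoff)
  cf$realized_predictive <-
    predictive_prognostic_effects(cf, dist, cutoff)$predictive
  cf
}

## closed-form cell probabilities for a step-function truth
solve_step_coefficients <- function(spec) {
  dist <- spec$dist
  cutoff <- spec$fixed_cutoff %||% bm_quantile(dist, 0.5)
  q <- bm_cdf(dist, cutoff)
  if (q <= 0 || q >= 1) stop("step cutoff leaves zero mass on one side")
  prog <- if (spec$predictive_effect > 0)
    spec$prognostic_fraction * spec$predictive_effect
  else spec$prognostic_magnitude
  ## unknowns (p0b, p0a, p1b, p1a)
  A <- rbind(c(q, 1 - q, 0, 0),        # control ORR
             c(-1, 1, 0, 0),           # prognostic effect
             c(0, 0, q, 1 - q),        # experimental ORR
             c(1, -1, -1, 1))          # predictive effect
  b <- c(spec$control_orr, prog, spec$experimental_orr, spec$predictive_effect)
  p <- solve(A, b)
  if (any(p < 0 | p > 1))
    stop(sprintf("step truth infeasible for %s: cell probabilities %s",
                 spec$label, paste(round(p, 3), collapse = ", ")))
  new_scenario_coefficients(NA_real_, NA_real_, NA_real_, NA_real_,
                            true_cutoff = cutoff, truth_form = "step",
                            step_params = list(cutoff = cutoff,
                                               p0_below = p[1], p0_above = p[2],
                                               p1_below = p[3], p1_above = p[4]))
}

#' Simulate one trial dataset from a solved scenario
#'
#' Draws `n1` experimental and `n0` control patients; biomarker values
#' i.i.d. from the scenario distribution, responses Bernoulli with the
#' truth's per-arm probability at the drawn value.  Fully reproducible
#' under `seed`.
#'
#' @param coeffs a `scenario_coefficients`.
#' @param spec the matching [scenario_spec()].
#' @param seed optional integer seed.
#' @return a [trial_data()] with exactly `n1 + n0` rows (experimental
#'   first).
#' @export
simulate_trial <- function(coeffs, spec, seed = NULL) {
  maybe_seed(seed)
  n <- spec$n1 + spec$n0
  arm <- rep(c(1L, 0L), c(spec$n1, spec$n0))
  x <- bm_sample(spec$dist, n)
  p <- ifelse(arm == 1L, truth_prob(coeffs, 1, x), truth_prob(coeffs, 0, x))
  y <- stats::rbinom(n, 1L, p)
  trial_data(sprintf("S%03d", seq_len(n)), arm, x, y)
}

#' Preset scenario grid of the simulation study
#'
#' The four null scenarios (NPNPNT, NPNPT, NPPNT, NPPT), the four
#' alternative bases with predictive effects 50/40/30/20% (HP_50, HP_40,
#' MP_30, LP_20) each without (NP), with moderate (MP, kappa 0.2) and
#' with high (HP, kappa 0.5) prognostic effect, crossed with the four
#' biomarker distributions of [preset_distributions()].
#'
#' @param distributions named list of [biomarker_dist()] objects.
#' @param labels optional subset of scenario labels.
#' @param n1,n0 arm sizes.
#' @param control_orr,experimental_orr marginal ORR targets.
#' @param prognostic_magnitude prognostic effect of the prognostic nulls.
#' @param truth_form `"logistic"` or `"step"`.
#' @return named list of [scenario_spec()] objects, names
#'   `<label>.<distribution>`.
#' @export
preset_scenarios <- function(distributions = preset_distributions(),
                             labels = NULL, n1 = 40, n0 = 20,
                             control_orr = 0.4, experimental_orr = 0.6,
                             prognostic_magnitude = 0.2,
                             truth_form = "logistic") {
  base <- list(
    NPNPNT = list(eo = control_orr, delta = 0, kappa = 0, prog = 0, cut = NULL),
    NPNPT  = list(eo = experimental_orr, delta = 0, kappa = 0, prog = 0, cut = NULL),
    NPPNT  = list(eo = control_orr, delta = 0, kappa = 0,
                  prog = prognostic_magnitude, cut = 17),
    NPPT   = list(eo = experimental_orr, delta = 0, kappa = 0,
                  prog = prognostic_magnitude, cut = 17)
  )
  alt_effects <- c(HP_50 = 0.50, HP_40 = 0.40, MP_30 = 0.30, LP_20 = 0.20)
  prog_levels <- c(NP = 0, MP = 0.2, HP = 0.5)
  for (a in names(alt_effects)) {
    pred_code <- sub("_.*", "", a)          # HP / MP / LP
    eff_code <- sub(".*_", "", a)           # 50 / 40 / 30 / 20
    for (pg in names(prog_levels)) {
      lab <- sprintf("%sP%sP_%s", substr(pred_code, 1, 1), substr(pg, 1, 1), eff_code)
      base[[lab]] <- list(eo = experimental_orr, delta = alt_effects[[a]],
                          kappa = prog_levels[[pg]], prog = 0, cut = NULL)
    }
  }
  if (!is.null(labels)) {
    unknown <- setdiff(labels, names(base))
    if (length(unknown)) stop("unknown scenario label(s): ",
                              paste(unknown, collapse = ", "))
    base <- base[labels]
  }
  out <- list()
  for (lab in names(base)) {
    b <- base[[lab]]
    for (dn in names(distributions)) {
      out[[paste(lab, dn, sep = ".")]] <-
        scenario_spec(lab, distributions[[dn]],
                      control_orr = control_orr, experimental_orr = b$eo,
                      predictive_effect = b$delta,
                      prognostic_fraction = b$kappa,
                      prognostic_magnitude = b$prog, fixed_cutoff = b$cut,
                      truth_form = truth_form, n1 = n1, n0 = n0)
    }
  }
  out
}

#' The four null scenario labels
#' @return character vector.
#' @export
null_labels <- function() c("NPNPNT", "NPNPT", "NPPNT", "NPPT")
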