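#' Arm-by-biomarker response models
#'
#' Both the AKSA test and the regression comparators model the binary
#' response as a function of treatment arm, biomarker and their
#' interaction on the logit scale,
#' `logit p = b0 + b1*T + b2*(X*T) + b3*X`.
#' Two backends are available: a plain maximum-likelihood logistic fit
#' ([fit_logistic_interaction()]) and a penalized-spline binomial GAM
#' ([fit_gam_interaction()]) that replaces the linear interaction term by
#' a smooth of the arm-specific biomarker value.
#'
#' @name response_models
NULL

## logistic ML fit on an explicit design matrix; returns coefficients,
## covariance, log-likelihood and degeneracy flags.  Used inside the
## simulation loops thousands of times, so the regular path is a tight
## Newton iteration on the normal equations; rank-deficient designs fall
## back to stats::glm.fit, which handles aliasing.  Must tolerate
## separation and rank deficiency without throwing.
logistic_ml <- function(X, y, max_iter = 100, tol = 1e-8) {
  out <- tryCatch(logistic_ml_newton(X, y, max_iter, tol),
                  error = function(e) NULL)
  if (is.null(out)) logistic_ml_glmfit(X, y) else out
}

## regular path; chol() throws on a rank-deficient crossproduct, caught
## once in logistic_ml
logistic_ml_newton <- function(X, y, max_iter = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  converged <- FALSE
  separated <- FALSE
  ch <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    score <- crossprod(X, y - mu)
    ch <- chol(crossprod(X, X * w))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    beta <- beta + chol2inv(ch) %*% score
    if (max(abs(beta)) > 50) {  # diverging linear predictor: separation
      separated <- TRUE
      break
    }
  }
  vcov <- chol2inv(ch)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  mu <- pmin(pmax(stats::plogis(as.numeric(X %*% beta)), 1e-12), 1 - 1e-12)
  loglik <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  se <- sqrt(pmax(diag(vcov), 0))
  separated <- separated || !converged || max(abs(beta)) > 50 || any(se > 500)
  list(coefficients = stats::setNames(as.numeric(beta), colnames(X)),
       vcov = vcov, loglik = loglik, converged = converged, rank = p,
       rank_deficient = FALSE, separated = separated,
       se = stats::setNames(se, colnames(X)))
}

## slow path: aliased / ill-conditioned designs
logistic_ml_glmfit <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  p <- ncol(X)
  rank <- fit$rank
  coefs <- fit$coefficients                     # NA for aliased columns
  vcov <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  if (rank > 0) {
    piv <- fit$qr$pivot[seq_len(rank)]
    cov_r <- chol2inv(fit$qr$qr[seq_len(rank), seq_len(rank), drop = FALSE])
    vcov[piv, piv] <- cov_r
  }
  mu <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
  loglik <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  se <- sqrt(pmax(diag(vcov), 0))
  finite <- is.finite(coefs)
  separated <- !fit$converged ||
    (any(finite) && max(abs(coefs[finite])) > 50) ||
    any(is.finite(se) & se > 500)
  list(coefficients = coefs, vcov = vcov, loglik = loglik,
       converged = fit$converged, rank = rank,
       rank_deficient = rank < p, separated = separated, se = se)
}

## design matrix (intercept, arm, biomarker, arm:biomarker [, covariates])
interaction_design <- function(data, interaction = TRUE, covariates = FALSE) {
  X <- cbind("(Intercept)" = 1, arm = data$arm, biomarker = data$biomarker)
  if (interaction) X <- cbind(X, "arm:biomarker" = data$arm * data$biomarker)
  if (covariates) {
    extra <- setdiff(names(data), c("subject_id", "arm", "biomarker", "response"))
    for (v in extra) {
      X <- cbind(X, data[[v]])
      colnames(X)[ncol(X)] <- v
    }
  }
  X
}

#' Fit the linear logistic arm-by-biomarker interaction model
#'
#' Maximum-likelihood fit of `response ~ arm + biomarker + arm:biomarker`
#' with a logit link.  Perfect separation and rank deficiency are flagged
#' on the returned object rather than raised, so simulation sweeps can
#' record a no-evidence result and continue.
#'
#' @param data a [trial_data()] object with both arms present.
#' @param covariates include extra covariate columns additively.
#' @return object of class `response_fit` with elements `coefficients`,
#'   `vcov`, `loglik`, `converged`, `separated`, `rank_deficient`.
#' @export
fit_logistic_interaction <- function(data, covariates = FALSE) {
  check_two_arms(data)
  if (all(data$response == 0L) || all(data$response == 1L))
    stop("need at least one response and one non-response")
  X <- interaction_design(data, interaction = TRUE, covariates = covariates)
  fit <- logistic_ml(X, data$response)
  structure(c(fit, list(backend = "linear_logistic",
                        formula = "response ~ arm + biomarker + arm:biomarker")),
            class = "response_fit")
}

## nested model without the interaction term, for the likelihood-ratio test
fit_logistic_main <- function(data, covariates = FALSE) {
  check_two_arms(data)
  X <- interaction_design(data, interaction = FALSE, covariates = covariates)
  fit <- logistic_ml(X, data$response)
  structure(c(fit, list(backend = "linear_logistic",
                        formula = "response ~ arm + biomarker")),
            class = "response_fit")
}

#' @export
print.response_fit <- function(x, ...) {
  cat("Response model (", x$backend, "): ", x$formula, "\n", sep = "")
  if (x$backend == "linear_logistic") {
    tab <- cbind(estimate = x$coefficients, se = x$se)
    print(round(tab, 4))
    if (x$separated) cat("  [flagged: separation / non-convergence]\n")
    if (x$rank_deficient) cat("  [flagged: rank-deficient design]\n")
  } else {
    cat("  penalized-spline GAM, basis dimension ", x$basis_dim, "\n", sep = "")
  }
  invisible(x)
}

#' Logit-scale prediction with pointwise standard error
#'
#' Evaluates the fitted per-arm predictor at biomarker value(s) `x`.  For
#' the linear backend the standard error is the delta-method form
#' `sqrt(d' V d)` with `d` the design vector and `V` the full coefficient
#' covariance; the GAM backend delegates to `mgcv`'s `predict(se.fit =
#' TRUE)`.
#'
#' @param model a `response_fit`.
#' @param arm 0 or 1.
#' @param x numeric vector of biomarker values.
#' @return list with numeric vectors `estimate` and `se`.
#' @export
predict_logit <- function(model, arm, x) {
  stopifnot(inherits(model, "response_fit"), arm %in% c(0, 1))
  if (model$backend == "gam") {
    nd <- data.frame(arm = rep(as.integer(arm), length(x)), biomarker = x)
    nd$xt <- nd$arm * nd$biomarker
    pr <- mgcv::predict.gam(model$gam, newdata = nd, type = "link", se.fit = TRUE)
    return(list(estimate = as.numeric(pr$fit), se = as.numeric(pr$se.fit)))
  }
  beta <- model$coefficients
  V <- model$vcov
  has_int <- length(beta) >= 4
  D <- cbind(1, arm, x, if (has_int) arm * x)
  if (length(beta) > ncol(D))  # covariate terms evaluated at zero
    D <- cbind(D, matrix(0, nrow(D), length(beta) - ncol(D)))
  beta0 <- ifelse(is.na(beta), 0, beta)
  est <- as.numeric(D %*% beta0)
  V0 <- V
  V0[is.na(V0)] <- 0
  se <- sqrt(pmax(rowSums((D %*% V0) * D), 0))
  list(estimate = est, se = se)
}

#' Fit the penalized-spline GAM backend
#'
#' Binomial GAM `response ~ arm + biomarker + s(arm * biomarker)` fitted by
#' penalized likelihood with a cubic regression spline basis of dimension
#' `basis_dim` (default 3) on the arm-specific biomarker term.  If the
#' smooth fit fails the linear logistic backend is returned with a
#' warning.
#'
#' @param data a [trial_data()] object.
#' @param basis_dim basis dimension of the smooth.
#' @return object of class `response_fit` (backend `"gam"`, or
#'   `"linear_logistic"` on fallback).
#' @export
fit_gam_interaction <- function(data, basis_dim = 3) {
  check_two_arms(data)
  df <- data.frame(response = data$response, arm = data$arm,
                   biomarker = data$biomarker, xt = data$arm * data$biomarker)
  g <- try(mgcv::gam(response ~ arm + biomarker + s(xt, k = basis_dim, bs = "cr"),
                     family = stats::binomial(), data = df, method = "REML"),
           silent = TRUE)
  if (inherits(g, "try-error") || !g$converged) {
    warning("GAM smoothing failed; falling back to the linear logistic backend")
    return(fit_logistic_interaction(data))
  }
  structure(list(backend = "gam", gam = g, basis_dim = basis_dim,
                 converged = g$converged, separated = FALSE,
                 rank_deficient = FALSE,
                 formula = "response ~ arm + biomarker + s(arm * biomarker)"),
            class = "response_fit")
}

#' Wald p-value of the interaction coefficient
#'
#' Two-sided normal p-value for `b2` (the `arm:biomarker` coefficient) of
#' a linear logistic fit.
#'
#' @param model a linear-logistic `response_fit`.
#' @return scalar p-value (1 when the fit is flagged).
#' @export
interaction_pvalue <- function(model) {
  stopifnot(inherits(model, "response_fit"), model$backend == "linear_logistic")
  b <- model$coefficients[["arm:biomarker"]]
  s <- model$se[["arm:biomarker"]]
  if (model$separated || model$rank_deficient || !is.finite(b) ||
      !is.finite(s) || s <= 0) return(1)
  2 * stats::pnorm(-abs(b) / s)
}
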