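#' Patient-level trial dataset
#'
#' Container for a two-arm trial with a continuous baseline biomarker and a
#' binary response.  A `trial_data` object is a validated `data.frame` with
#' columns `subject_id`, `arm` (0 = control, 1 = experimental),
#' `biomarker` (continuous, nominally on `[0, 100]` but unbounded values are
#' accepted) and `response` (0/1), plus any extra numeric covariate columns.
#'
#' @param subject_id vector of unique labels (coerced to character).
#' @param arm integer/numeric vector of 0/1 treatment indicators.
#' @param biomarker numeric vector of biomarker values.
#' @param response integer/numeric vector of 0/1 responses.
#' @param covariates optional data.frame of numeric covariates.
#' @return a `data.frame` of class `trial_data`.
#' @examples
#' td <- trial_data(1:6, rep(c(1, 0), 3), c(10, 20, 30, 40, 50, 60),
#'                  c(1, 0, 1, 1, 0, 0))
#' arm_sizes(td)
#' @export
trial_data <- function(subject_id, arm, biomarker, response, covariates = NULL) {
  df <- data.frame(subject_id = as.character(subject_id),
                   arm = arm, biomarker = biomarker, response = response,
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == nrow(df))
    df <- cbind(df, covariates)
  }
  validate_trial_data(df)
}

#' Validate a trial dataset
#'
#' Checks the column contract and value ranges; errors name the first
#' offending row.  Row order is preserved.
#'
#' @param df a data.frame with the mandatory columns.
#' @return the validated data.frame with class `trial_data` prepended.
#' @export
validate_trial_data <- function(df) {
  needed <- c("subject_id", "arm", "biomarker", "response")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stop("empty dataset")

  bad_row <- function(ok, what) {
    if (!all(ok)) stop(sprintf("invalid %s at row %d", what, which(!ok)[1]))
  }
  if (!is.numeric(df$arm)) df$arm <- suppressWarnings(as.numeric(df$arm))
  if (!is.numeric(df$response)) df$response <- suppressWarnings(as.numeric(df$response))
  if (!is.numeric(df$biomarker)) df$biomarker <- suppressWarnings(as.numeric(df$biomarker))
  bad_row(!is.na(df$arm) & df$arm %in% c(0, 1), "arm (must be 0/1)")
  bad_row(!is.na(df$response) & df$response %in% c(0, 1), "response (must be 0/1)")
  bad_row(is.finite(df$biomarker), "biomarker (must be finite numeric)")
  df$arm <- as.integer(df$arm)
  df$response <- as.integer(df$response)
  class(df) <- unique(c("trial_data", class(df)))
  df
}

#' @export
print.trial_data <- function(x, ...) {
  ns <- arm_sizes(x)
  cat(sprintf("Trial dataset: %d patients (%d experimental : %d control)\n",
              nrow(x), ns[["n1"]], ns[["n0"]]))
  cat(sprintf("  biomarker range [%.3g, %.3g]; overall response rate %.3f\n",
              min(x$biomarker), max(x$biomarker), mean(x$response)))
  invisible(x)
}

#' Arm sizes of a trial dataset
#'
#' @param data a [trial_data()] object.
#' @return named vector `c(n1 = ..., n0 = ...)` (experimental, control).
#' @export
arm_sizes <- function(data) {
  c(n1 = sum(data$arm == 1L), n0 = sum(data$arm == 0L))
}

## both arms present, required by every two-arm method
check_two_arms <- function(data) {
  ns <- arm_sizes(data)
  if (any(ns == 0)) stop("both arms must be present")
  invisible(ns)
}

#' Read / write a trial dataset as CSV
#'
#' The CSV contract is comma-separated, dot decimal, UTF-8, with header
#' columns `subject_id, arm, biomarker, response` (extra columns are kept
#' as covariates).  Writing uses 15 significant digits so round-trips are
#' lossless.
#'
#' @param path file path.
#' @param data a [trial_data()] object.
#' @return `read_trial_csv` returns a validated [trial_data()];
#'   `write_trial_csv` returns `path` invisibly.
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$subject_id <- as.character(df$subject_id)
  validate_trial_data(df)
}

#' @rdname read_trial_csv
#' @export
write_trial_csv <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  out <- as.data.frame(data)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) format(v, digits = 15, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
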