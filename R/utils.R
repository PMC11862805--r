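#' Derive reproducible sub-seeds from a master seed
#'
#' Simulation sweeps (calibration, operating characteristics) need one
#' independent random stream per scenario cell or replicate.  A single
#' master seed is expanded into a deterministic vector of sub-seeds, each
#' usable with [set.seed()].  Values stay strictly below 2^31.
#'
#' @param master integer master seed.
#' @param n number of sub-seeds required.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

## set.seed only when the caller supplied one; NULL leaves the stream alone
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
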