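#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft rnorm sd pt pf ptukey lm approx median var
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Internal error helper: consistent condition class for validation failures.
abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("oxyclock_validation_error", "error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Derive a reproducible child seed from a root seed and stream labels
#'
#' All randomness in the package flows from one root seed; independent
#' random streams (per scenario, replicate, purpose) get their own child
#' seed via a deterministic integer hash, so that regenerating any single
#' trace does not depend on the order in which other traces were drawn.
#'
#' @param seed Integer root seed.
#' @param ... Additional stream labels (coerced to character).
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  if (!is_scalar_number(seed)) abort_validation("`seed` must be a single finite number")
  m <- 2147483629  # large prime < 2^31
  h <- as.numeric(seed) %% m
  for (part in list(...)) {
    for (ch in utf8ToInt(paste(as.character(part), collapse = "|"))) {
      h <- (h * 131 + ch) %% m
    }
    h <- (h * 131 + 7) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

# Sampling interval (h) of a uniform grid; errors if grid is not uniform
# within `rel_tol` relative to the median step.
uniform_step_h <- function(time_h, rel_tol = 1e-6, context = "time series") {
  if (length(time_h) < 2) abort_validation(paste(context, "needs at least 2 time points"))
  dt <- diff(time_h)
  step <- stats::median(dt)
  if (step <= 0 || any(abs(dt - step) > rel_tol * step)) {
    abort_validation(paste0(
      context, " is not uniformly sampled; resample or segment before spectral analysis"
    ))
  }
  step
}
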