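# Shared fixtures and independent oracles for the test suite.

# Uniformly sampled cosine trace: mesor + amp * cos(2*pi*(t - peak_at)/tau).
cosine_ts <- function(tau_h, duration_h = 96, step_min = 5, mesor = 0,
                      amplitude = 1, peak_at = 0, noise_sd = 0, seed = NULL) {
  t <- seq(0, duration_h, by = step_min / 60)
  x <- mesor + amplitude * cos(2 * pi * (t - peak_at) / tau_h)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + rnorm(length(t), 0, noise_sd)
  }
  oxy_ts(t, x)
}

# Independent DFT oracle: direct O(n^2) summation, no stats::fft. Returns
# the one-sided folded power spectrum under the package's normalisation
# (sum over bins == sum of squares for an unpadded, untapered series).
direct_dft_power <- function(x) {
  n <- length(x)
  half <- floor(n / 2)
  j <- seq_len(n) - 1
  p <- vapply(0:half, function(k) {
    re <- sum(x * cos(2 * pi * j * k / n))
    im <- -sum(x * sin(2 * pi * j * k / n))
    (re^2 + im^2) / n
  }, numeric(1))
  interior <- (0:half) > 0 & (0:half) < n / 2
  p[interior] <- 2 * p[interior]
  p
}

# Closed-form least-squares projection of y onto {1, t}: independent of
# the package's detrend implementation (explicit 2x2 normal equations).
line_projection <- function(t, y) {
  s0 <- length(t); s1 <- sum(t); s2 <- sum(t^2)
  b0 <- sum(y); b1 <- sum(t * y)
  det <- s0 * s2 - s1^2
  a <- (s2 * b0 - s1 * b1) / det
  b <- (s0 * b1 - s1 * b0) / det
  a + b * t
}

# Minimal well-formed Ct table for delta-delta-Ct identity checks.
tiny_ct_table <- function() {
  tibble::tibble(
    sample_id = rep(c("s1", "cal"), each = 2),
    gene = rep(c("TGT", "HKG"), 2),
    clock_time = "06:30",
    condition = "LD",
    spectrum = "blue",
    replicate = 1L,
    ct = c(24, 20, 26, 20)
  )
}
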