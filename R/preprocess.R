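#' Subtract a medium-only blank channel from a sample trace
#'
#' The blank flask (no algae) records the shared optode/medium drift;
#' subtracting it point-by-point removes that drift from the biological
#' signal. Timestamps must align within half the median sampling interval;
#' by default no interpolation is performed (set `interpolate = TRUE` to
#' linearly interpolate the blank onto the sample grid).
#'
#' @param sample,blank [oxy_ts()] objects; `blank` must cover the sample's
#'   time range.
#' @param interpolate Linearly interpolate the blank onto the sample grid
#'   instead of requiring aligned timestamps.
#' @return An `oxy_ts` of `sample - blank` on the sample grid; the blank
#'   channel used is recorded in the `blank_channel` attribute.
#' @export
blank_correct <- function(sample, blank, interpolate = FALSE) {
  stopifnot(inherits(sample, "oxy_ts"), inherits(blank, "oxy_ts"))
  if (min(blank$time_h) > min(sample$time_h) + 1e-9 ||
      max(blank$time_h) < max(sample$time_h) - 1e-9) {
    abort_validation("blank trace does not cover the sample's time range")
  }
  if (interpolate) {
    bvals <- stats::approx(blank$time_h, blank$values, xout = sample$time_h)$y
  } else {
    tol <- uniform_step_h(sample$time_h, rel_tol = Inf, context = "sample") / 2
    idx <- findInterval(sample$time_h, blank$time_h - tol)
    ok <- idx >= 1 & idx <= length(blank$time_h) &
      abs(blank$time_h[pmin(pmax(idx, 1), length(blank$time_h))] - sample$time_h) <= tol
    if (!all(ok)) {
      abort_validation(paste0(
        "blank and sample grids are misaligned beyond half a sampling interval ",
        "(first mismatch at sample row ", which(!ok)[1],
        "); pass interpolate = TRUE to resample the blank"
      ))
    }
    bvals <- blank$values[idx]
  }
  out <- oxy_ts(sample$time_h, sample$values - bvals,
                channel_id = sample$channel_id, is_blank = FALSE,
                regime = sample$regime, segment_label = sample$segment_label)
  attr(out, "blank_channel") <- blank$channel_id
  out
}

#' Remove a constant or linear trend from a trace
#'
#' Spectral analysis of a short record needs the mean (and any residual
#' instrument drift) removed, otherwise low-frequency leakage dominates
#' the circadian band.
#'
#' @param ts An [oxy_ts()].
#' @param method `"linear"` (least-squares line removed), `"mean"`, or
#'   `"none"`.
#' @return A detrended `oxy_ts`.
#' @export
detrend <- function(ts, method = c("linear", "mean", "none")) {
  stopifnot(inherits(ts, "oxy_ts"))
  method <- match.arg(method)
  values <- switch(method,
    none = ts$values,
    mean = ts$values - mean(ts$values),
    linear = {
      if (length(ts$time_h) < 3) {
        abort_validation("linear detrend needs at least 3 points")
      }
      stats::lm.fit(cbind(1, ts$time_h), ts$values)$residuals
    }
  )
  out <- ts
  out$values <- as.numeric(values)
  out
}

#' Regularise a trace with missing sampling intervals
#'
#' The spectral estimator requires a uniform grid. Short dropouts (at
#' most `max_gap_intervals` missing sampling steps) are filled by linear
#' interpolation; at any longer gap the trace is split, because inventing
#' hours of signal would bias the periodogram. Gaps are thus always
#' explicit: the result is one or more uniformly sampled pieces.
#'
#' @param ts An [oxy_ts()] whose timestamps are on a regular grid except
#'   for missing rows.
#' @param max_gap_intervals Longest gap (in sampling intervals) that may
#'   be interpolated rather than split (default 3).
#' @return A list of uniformly sampled `oxy_ts` pieces (length 1 if no
#'   split was needed).
#' @export
fill_gaps <- function(ts, max_gap_intervals = 3) {
  stopifnot(inherits(ts, "oxy_ts"))
  d <- diff(ts$time_h)
  step <- stats::median(d)
  if (step <= 0) abort_validation("cannot infer a sampling interval")
  steps <- round(d / step)
  if (any(abs(d / step - steps) > 1e-6)) {
    abort_validation("timestamps are not aligned to a common sampling grid")
  }
  piece_id <- cumsum(c(0, steps > max_gap_intervals))
  pieces <- lapply(split(seq_along(ts$time_h), piece_id), function(idx) {
    t_obs <- ts$time_h[idx]
    grid <- seq(t_obs[1], t_obs[length(t_obs)], by = step)
    vals <- stats::approx(t_obs, ts$values[idx], xout = grid)$y
    oxy_ts(grid, vals, channel_id = ts$channel_id, is_blank = ts$is_blank,
           regime = ts$regime, segment_label = ts$segment_label)
  })
  names(pieces) <- NULL
  pieces
}

#' Split a trace into light-regime phase segments
#'
#' Each regime phase (e.g. the LD entrainment block, then the LL free run)
#' maps to the slice of the trace recorded during it; entrained and
#' free-running periods are then estimated segment-wise. Optionally the
#' first `skip_transition_h` hours after every mode switch are excluded,
#' for analyses that want to drop the transient right after lights change.
#'
#' @param ts An [oxy_ts()].
#' @param regime A [light_regime()] covering the whole trace (defaults to
#'   the regime attached to the trace).
#' @param skip_transition_h Hours to drop at the start of every phase
#'   after the first (default 0: headline estimates use full segments).
#' @return A `segmented_series`: a named list of `oxy_ts` segments
#'   (labels like `LD-1`, `LL-1`) with a `windows` attribute.
#' @export
segment <- function(ts, regime = ts$regime, skip_transition_h = 0) {
  stopifnot(inherits(ts, "oxy_ts"))
  if (is.null(regime)) abort_validation("no regime attached to the trace or supplied")
  regime <- validate_regime(regime)
  if (max(ts$time_h) > regime_total_h(regime) + 1e-9) {
    abort_validation("trace extends beyond the regime's total duration")
  }
  starts <- phase_starts(regime)
  ends <- starts + regime$duration_h
  labels <- phase_labels(regime)
  segments <- list()
  windows <- list()
  for (i in seq_len(nrow(regime))) {
    lo <- starts[i] + if (i > 1) skip_transition_h else 0
    hi <- ends[i]
    sel <- ts$time_h >= lo - 1e-9 &
      (ts$time_h < hi - 1e-9 | (i == nrow(regime) & ts$time_h <= hi + 1e-9))
    if (!any(sel)) next
    seg <- oxy_ts(ts$time_h[sel], ts$values[sel], channel_id = ts$channel_id,
                  is_blank = ts$is_blank, regime = regime,
                  segment_label = labels[i])
    segments[[labels[i]]] <- seg
    windows[[labels[i]]] <- tibble::tibble(
      label = labels[i], mode = regime$mode[i], start_h = lo, end_h = hi,
      n_points = sum(sel)
    )
  }
  structure(segments, windows = dplyr::bind_rows(windows),
            class = "segmented_series")
}

#' @export
print.segmented_series <- function(x, ...) {
  w <- attr(x, "windows")
  cat("<segmented_series>\n")
  print(w)
  invisible(x)
}
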