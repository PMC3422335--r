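#' Light-regime phases
#'
#' A light regime is an ordered sequence of experimental phases: light:dark
#' cycling (`LD`), constant light (`LL`) or constant darkness (`DD`), each
#' with a spectrum (`full`, `blue`, `green`, `red`), an irradiance in
#' umol quanta m-2 s-1, a photoperiod (hours of light per 24 h; meaningful
#' only for LD) and a duration in hours. Within an LD phase the cycle is
#' anchored at the phase start with the light interval first.
#'
#' @param mode One of `"LD"`, `"LL"`, `"DD"`.
#' @param spectrum One of `"full"`, `"blue"`, `"green"`, `"red"`.
#' @param irradiance Irradiance (umol quanta m-2 s-1), non-negative.
#' @param photoperiod_light_h Hours of light per 24 h cycle, in (0, 24);
#'   only used when `mode = "LD"` (default 12, i.e. 12:12).
#' @param duration_h Phase duration in hours, positive.
#' @return A one-row tibble describing the phase.
#' @export
light_phase <- function(mode, spectrum = "full", irradiance = 50,
                        photoperiod_light_h = if (identical(mode, "LD")) 12 else NA_real_,
                        duration_h = 48) {
  tibble::tibble(
    mode = as.character(mode),
    spectrum = as.character(spectrum),
    irradiance = as.numeric(irradiance),
    photoperiod_light_h = as.numeric(photoperiod_light_h),
    duration_h = as.numeric(duration_h)
  )
}

#' Construct and validate a light regime
#'
#' @param ... One-row phase tibbles from [light_phase()], or a single data
#'   frame of phases.
#' @return A `light_regime`: a tibble of ordered phases.
#' @export
light_regime <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.data.frame(parts[[1]]) &&
      !inherits(parts[[1]], "light_regime")) {
    phases <- tibble::as_tibble(parts[[1]])
  } else {
    phases <- dplyr::bind_rows(parts)
  }
  validate_regime(phases)
}

#' @rdname light_regime
#' @param phases A data frame of phases.
#' @export
validate_regime <- function(phases) {
  phases <- tibble::as_tibble(phases)
  required <- c("mode", "spectrum", "irradiance", "photoperiod_light_h", "duration_h")
  missing <- setdiff(required, names(phases))
  if (length(missing)) {
    abort_validation(paste("regime is missing columns:", paste(missing, collapse = ", ")))
  }
  if (nrow(phases) == 0) abort_validation("regime must contain at least one phase")
  bad_mode <- setdiff(unique(phases$mode), c("LD", "LL", "DD"))
  if (length(bad_mode)) {
    abort_validation(paste("unknown regime mode:", paste(bad_mode, collapse = ", ")))
  }
  bad_spec <- setdiff(unique(phases$spectrum), c("full", "blue", "green", "red"))
  if (length(bad_spec)) {
    abort_validation(paste("unknown spectrum:", paste(bad_spec, collapse = ", ")))
  }
  if (any(!is.finite(phases$duration_h)) || any(phases$duration_h <= 0)) {
    abort_validation("every phase duration_h must be a positive, finite number of hours")
  }
  if (any(phases$irradiance < 0, na.rm = TRUE)) {
    abort_validation("irradiance must be non-negative")
  }
  ld <- phases$mode == "LD"
  pp <- phases$photoperiod_light_h[ld]
  if (any(!is.finite(pp)) || any(pp <= 0) || any(pp >= 24)) {
    abort_validation("photoperiod_light_h must lie in (0, 24) for LD phases")
  }
  class(phases) <- c("light_regime", class(tibble::tibble()))
  phases
}

#' Total duration of a regime in hours
#' @param regime A `light_regime`.
#' @export
regime_total_h <- function(regime) sum(regime$duration_h)

# Start time (h) of each phase.
phase_starts <- function(regime) cumsum(c(0, regime$duration_h))[seq_len(nrow(regime))]

# Human-readable per-phase labels: mode plus occurrence number (LD-1, LL-1, ...).
phase_labels <- function(regime) {
  paste0(regime$mode, "-", stats::ave(seq_len(nrow(regime)), regime$mode, FUN = seq_along))
}

# Logical: is the light on at time t (hours since experiment start)?
# LL is always-on light, DD always off; within LD the cycle starts with the
# light interval at the phase start.
light_on <- function(regime, t) {
  starts <- phase_starts(regime)
  ends <- starts + regime$duration_h
  out <- rep(NA, length(t))
  for (i in seq_len(nrow(regime))) {
    sel <- t >= starts[i] & (t < ends[i] | (i == nrow(regime) & t <= ends[i]))
    if (!any(sel)) next
    out[sel] <- switch(regime$mode[i],
      LL = TRUE,
      DD = FALSE,
      LD = ((t[sel] - starts[i]) %% 24) < regime$photoperiod_light_h[i]
    )
  }
  out
}

#' Read / write a light regime as a YAML config
#'
#' The config is a mapping with a `phases` list; each phase carries `mode`,
#' `spectrum`, `irradiance`, `photoperiod_light_h` (LD only) and
#' `duration_h`.
#'
#' @param path File path.
#' @return `read_regime()` returns a validated `light_regime`.
#' @export
read_regime <- function(path) {
  if (!file.exists(path)) abort_validation(paste("regime file not found:", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$phases) || length(cfg$phases) == 0) {
    abort_validation("regime config must contain a non-empty `phases` list")
  }
  phases <- dplyr::bind_rows(lapply(cfg$phases, function(p) {
    tibble::tibble(
      mode = as.character(p$mode %||% NA_character_),
      spectrum = as.character(p$spectrum %||% "full"),
      irradiance = as.numeric(p$irradiance %||% NA_real_),
      photoperiod_light_h = as.numeric(p$photoperiod_light_h %||% NA_real_),
      duration_h = as.numeric(p$duration_h %||% NA_real_)
    )
  }))
  validate_regime(phases)
}

#' @rdname read_regime
#' @param regime A `light_regime`.
#' @export
write_regime <- function(regime, path) {
  regime <- validate_regime(regime)
  phases <- lapply(seq_len(nrow(regime)), function(i) {
    p <- as.list(regime[i, ])
    if (is.na(p$photoperiod_light_h)) p$photoperiod_light_h <- NULL
    p
  })
  yaml::write_yaml(list(phases = phases), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
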