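# Deterministic (noise-free) oscillator evaluated on a time grid.
# Returns the oscillatory deviation A(t) * cos(phi(t)) plus mesor and drift.
#
# Phase bookkeeping: during an LD phase the oscillator is phase-locked to
# the forcing -- phi is anchored so that cos peaks at the middle of the
# light interval of the first forced cycle and advances at
# 2*pi/tau_entrained_h. At the switch to LL (or DD) the phase continues
# without a jump and advances at 2*pi/tau_rep: the free run starts from
# the entrained phase. Amplitude damping counts completed free-running
# cycles from the first switch to constant conditions.
oscillator_signal <- function(regime, rhythm, tau_rep, t) {
  starts <- phase_starts(regime)
  ends <- starts + regime$duration_h
  phi <- numeric(length(t))
  damp_cycles <- numeric(length(t))
  phi_cursor <- rhythm$phase0_rad
  free_cycles_before <- 0
  for (i in seq_len(nrow(regime))) {
    sel <- t >= starts[i] & (t < ends[i] | (i == nrow(regime) & t <= ends[i]))
    mode <- regime$mode[i]
    if (mode == "LD") {
      t_peak0 <- starts[i] + regime$photoperiod_light_h[i] / 2
      if (any(sel)) phi[sel] <- 2 * pi * (t[sel] - t_peak0) / rhythm$tau_entrained_h
      if (any(sel)) damp_cycles[sel] <- free_cycles_before
      phi_cursor <- 2 * pi * (ends[i] - t_peak0) / rhythm$tau_entrained_h
    } else {
      if (any(sel)) {
        phi[sel] <- phi_cursor + 2 * pi * (t[sel] - starts[i]) / tau_rep
        damp_cycles[sel] <- free_cycles_before + floor((t[sel] - starts[i]) / tau_rep)
      }
      phi_cursor <- phi_cursor + 2 * pi * regime$duration_h[i] / tau_rep
      free_cycles_before <- free_cycles_before + floor(regime$duration_h[i] / tau_rep)
    }
  }
  osc <- rhythm$amplitude * rhythm$damping_per_cycle^damp_cycles * cos(phi)
  if (isTRUE(rhythm$gate_dark)) {
    osc <- osc * as.numeric(light_on(regime, t))
  }
  rhythm$mesor + rhythm$drift_slope * t + osc
}

# Shared validated time grid for a scenario.
sampling_grid <- function(regime, sampling_interval_min) {
  if (!is_scalar_number(sampling_interval_min) || sampling_interval_min <= 0) {
    abort_validation("sampling_interval_min must be a positive number")
  }
  if (abs(60 %% sampling_interval_min) > 1e-9) {
    abort_validation("sampling_interval_min must divide 60")
  }
  total_h <- regime_total_h(regime)
  if (total_h < 24) {
    abort_validation("regime total duration must be at least 24 h for simulation")
  }
  step_h <- sampling_interval_min / 60
  seq(0, total_h, by = step_h)
}

#' Simulate one replicate oxygen-evolution trace
#'
#' Generates `mesor + drift_slope * t + A(t) * cos(phi(t)) + eps` on a
#' uniform grid (default one point per 5 min, the optode logging
#' interval). See [rhythm_model()] for the phase and damping model. The
#' free-running period of the replicate is drawn once per replicate from
#' `Normal(tau_free_h, replicate_tau_sd_h)`; all randomness is a
#' deterministic function of `(scenario, replicate_index, seed)`, so the
#' identical call reproduces the identical trace.
#'
#' @param scn A [scenario()].
#' @param replicate_index Replicate number (1-based).
#' @param sampling_interval_min Sampling interval in minutes; must divide 60.
#' @param seed Integer root seed.
#' @return An [oxy_ts()] with the scenario regime attached.
#' @export
simulate_oxygen_series <- function(scn, replicate_index, sampling_interval_min = 5,
                                   seed = 1) {
  stopifnot(inherits(scn, "scenario"))
  t <- sampling_grid(scn$regime, sampling_interval_min)
  rhythm <- scn$rhythm
  tau_rep <- rhythm$tau_free_h
  if (rhythm$replicate_tau_sd_h > 0) {
    set.seed(derive_seed(seed, scn$id, replicate_index, "tau"))
    tau_rep <- stats::rnorm(1, rhythm$tau_free_h, rhythm$replicate_tau_sd_h)
  }
  values <- oscillator_signal(scn$regime, rhythm, tau_rep, t)
  if (rhythm$noise_sd > 0) {
    set.seed(derive_seed(seed, scn$id, replicate_index, "noise"))
    values <- values + stats::rnorm(length(t), 0, rhythm$noise_sd)
  }
  ts <- oxy_ts(t, values, channel_id = paste0(scn$id, "-r", replicate_index),
               regime = scn$regime)
  attr(ts, "tau_rep_h") <- tau_rep
  ts
}

#' Simulate the medium-only blank channel of a scenario run
#'
#' The blank flask contains no algae: its trace is
#' `mesor_blank + drift_slope * t + eps` on the same timestamps as the
#' matching sample traces, so that subtracting it removes the shared
#' probe/medium drift.
#'
#' @inheritParams simulate_oxygen_series
#' @return An [oxy_ts()] flagged as blank.
#' @export
simulate_blank_series <- function(scn, sampling_interval_min = 5, seed = 1) {
  stopifnot(inherits(scn, "scenario"))
  t <- sampling_grid(scn$regime, sampling_interval_min)
  rhythm <- scn$rhythm
  values <- rhythm$mesor_blank + rhythm$drift_slope * t
  if (rhythm$noise_sd > 0) {
    set.seed(derive_seed(seed, scn$id, "blank"))
    values <- values + stats::rnorm(length(t), 0, rhythm$noise_sd)
  }
  oxy_ts(t, values, channel_id = paste0(scn$id, "-blank"), is_blank = TRUE,
         regime = scn$regime)
}
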