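#' Rhythm model parameters for the oxygen-evolution generator
#'
#' The generator writes traces of the form
#' `mesor + drift_slope * t + A(t) * cos(phi(t)) + noise`, where the phase
#' `phi` advances at `2*pi/tau_entrained_h` during LD phases (anchored so
#' the daily maximum falls inside the light interval) and at
#' `2*pi/tau_rep` during LL free run, with `tau_rep` drawn once per
#' replicate from `Normal(tau_free_h, replicate_tau_sd_h)`. The amplitude
#' is damped by `damping_per_cycle` for every completed free-running cycle
#' after the switch to constant light, emulating the observed fading of the
#' oxygen rhythm after the first day of LL.
#'
#' @param tau_entrained_h Period under LD forcing (h).
#' @param tau_free_h Free-running period tau under LL (h); must satisfy the
#'   circadian criterion band 19-28 h.
#' @param mesor Baseline oxygen level (instrument units).
#' @param amplitude Peak deviation from the mesor (instrument units, >= 0).
#' @param damping_per_cycle Multiplicative amplitude factor per completed
#'   LL cycle, in (0, 1].
#' @param phase0_rad Phase at t = 0 for regimes that do not start with an
#'   LD phase.
#' @param drift_slope Instrument/medium drift (units per hour).
#' @param noise_sd Gaussian measurement noise SD (instrument units, >= 0).
#' @param replicate_tau_sd_h Between-replicate SD of the free-running
#'   period (h, >= 0).
#' @param mesor_blank Baseline of the medium-only blank channel.
#' @param gate_dark If `TRUE`, the oscillatory component is suppressed to
#'   the mesor during dark intervals of LD phases (square-ish gating of
#'   photosynthetic oxygen production). Off by default: the analysis
#'   targets the fundamental period and the published traces show a
#'   continuous oscillation.
#' @return A `rhythm_model` list.
#' @export
rhythm_model <- function(tau_entrained_h = 24, tau_free_h = 24,
                         mesor = 100, amplitude = 30,
                         damping_per_cycle = 0.85, phase0_rad = 0,
                         drift_slope = 0.05, noise_sd = 3,
                         replicate_tau_sd_h = 0.2, mesor_blank = 90,
                         gate_dark = FALSE) {
  if (tau_free_h < 19 || tau_free_h > 28) {
    abort_validation("tau_free_h must lie in the circadian criterion band [19, 28] h")
  }
  if (amplitude < 0) abort_validation("amplitude must be >= 0")
  if (damping_per_cycle <= 0 || damping_per_cycle > 1) {
    abort_validation("damping_per_cycle must lie in (0, 1]")
  }
  if (noise_sd < 0) abort_validation("noise_sd must be >= 0")
  if (replicate_tau_sd_h < 0) abort_validation("replicate_tau_sd_h must be >= 0")
  structure(
    list(tau_entrained_h = tau_entrained_h, tau_free_h = tau_free_h,
         mesor = mesor, amplitude = amplitude,
         damping_per_cycle = damping_per_cycle, phase0_rad = phase0_rad,
         drift_slope = drift_slope, noise_sd = noise_sd,
         replicate_tau_sd_h = replicate_tau_sd_h, mesor_blank = mesor_blank,
         gate_dark = gate_dark),
    class = "rhythm_model"
  )
}

#' Experimental scenario: organism, light regime and rhythm ground truth
#'
#' @param id Short scenario label, unique within a scenario table.
#' @param organism `"culture"` (free-living dinoflagellate culture) or
#'   `"coral"` (symbiont in hospite).
#' @param regime A [light_regime()].
#' @param rhythm A [rhythm_model()].
#' @param n_replicates Number of replicate flasks / coral fragments.
#' @return A `scenario` list.
#' @export
scenario <- function(id, organism = c("culture", "coral"), regime, rhythm,
                     n_replicates = 4) {
  organism <- match.arg(organism)
  regime <- validate_regime(regime)
  if (n_replicates < 1) abort_validation("n_replicates must be >= 1")
  structure(
    list(id = id, organism = organism, regime = regime, rhythm = rhythm,
         n_replicates = n_replicates),
    class = "scenario"
  )
}

#' Packaged study scenarios
#'
#' One row per experimental condition of the study design: dinoflagellate
#' cultures under full-spectrum light at three irradiances, cultures under
#' blue/green/red LED light at 50 and 25 umol quanta m-2 s-1, and coral
#' fragments under blue/green/red light at 50 umol quanta m-2 s-1. The
#' ground-truth entrained and free-running periods (and their
#' between-replicate SDs) are the published values for those conditions.
#'
#' @return A tibble with columns `id`, `organism`, `spectrum`,
#'   `irradiance`, `tau_entrained_h`, `tau_free_h`, `replicate_tau_sd_h`.
#' @export
scenario_table <- function() {
  tibble::tribble(
    ~id,  ~organism, ~spectrum, ~irradiance, ~tau_entrained_h, ~tau_free_h, ~replicate_tau_sd_h,
    "S1",  "culture", "full",  100, 24.0,  23.6,  0.35,
    "S2",  "culture", "full",   75, 24.0,  24.38, 0.14,
    "S3",  "culture", "full",   50, 24.05, 25.3,  0.17,
    "S4",  "culture", "blue",   50, 24.5,  23.5,  0.17,
    "S5",  "culture", "blue",   25, 24.0,  24.4,  0.10,
    "S6",  "culture", "red",    50, 24.0,  23.5,  0.11,
    "S7",  "culture", "red",    25, 24.0,  22.7,  0.40,
    "S8",  "culture", "green",  50, 24.0,  22.7,  0.21,
    "S9",  "coral",   "blue",   50, 24.1,  23.8,  0.14,
    "S10", "coral",   "red",    50, 24.6,  25.1,  0.19,
    "S11", "coral",   "green",  50, 24.4,  22.76, 0.15
  )
}

#' Build a full scenario object from a packaged scenario id
#'
#' The default regime is 72 h of 12:12 LD entrainment followed by 96 h of
#' constant light: three entrained cycles and four free-running cycles, at
#' the scenario's spectrum and irradiance. Three LD cycles is the minimum
#' for a well-posed windowed periodogram estimate of the entrained period;
#' with only two cycles the spectral peak overlaps the DC/mirror lobes of
#' the taper and the entrained-period estimate is biased by hours.
#'
#' @param id A scenario id from [scenario_table()].
#' @param ld_duration_h,ll_duration_h Regime phase durations (h).
#' @param ... Overrides passed to [rhythm_model()] (e.g. `noise_sd = 0`).
#' @return A [scenario()].
#' @export
get_scenario <- function(id, ld_duration_h = 72, ll_duration_h = 96, ...) {
  tab <- scenario_table()
  row <- tab[tab$id == id, ]
  if (nrow(row) != 1) {
    abort_validation(paste0(
      "unknown scenario id '", id, "'; available: ",
      paste(tab$id, collapse = ", ")
    ))
  }
  regime <- light_regime(
    light_phase("LD", spectrum = row$spectrum, irradiance = row$irradiance,
                photoperiod_light_h = 12, duration_h = ld_duration_h),
    light_phase("LL", spectrum = row$spectrum, irradiance = row$irradiance,
                duration_h = ll_duration_h)
  )
  overrides <- list(...)
  args <- list(tau_entrained_h = row$tau_entrained_h,
               tau_free_h = row$tau_free_h,
               replicate_tau_sd_h = row$replicate_tau_sd_h)
  args[names(overrides)] <- overrides
  scenario(id = row$id, organism = row$organism, regime = regime,
           rhythm = do.call(rhythm_model, args), n_replicates = 4)
}
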