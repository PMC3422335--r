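#' Simulate and write a scenario run to disk
#'
#' Writes one CSV trace per replicate flask/fragment plus the shared
#' medium-only blank channel, the light-regime config, and a run manifest
#' (YAML) recording everything needed to regenerate the files
#' bit-identically: scenario id, root seed, replicate count, sampling
#' interval and the regime phases. The manifest timestamp is metadata
#' only; no output depends on it.
#'
#' @param scenario_id A packaged scenario id (see [scenario_table()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Root seed.
#' @param replicates Number of replicate traces (default: the scenario's).
#' @param sampling_interval_min Sampling interval in minutes.
#' @return Invisibly, the manifest as a list (with a `files` entry).
#' @export
write_scenario_run <- function(scenario_id, out_dir, seed = 1,
                               replicates = NULL, sampling_interval_min = 5) {
  scn <- get_scenario(scenario_id)
  replicates <- replicates %||% scn$n_replicates
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (r in seq_len(replicates)) {
    ts <- simulate_oxygen_series(scn, r, sampling_interval_min, seed)
    f <- file.path(out_dir, sprintf("%s_rep%d.csv", scenario_id, r))
    write_timeseries(ts, f)
    files <- c(files, f)
  }
  blank <- simulate_blank_series(scn, sampling_interval_min, seed)
  fb <- file.path(out_dir, sprintf("%s_blank.csv", scenario_id))
  write_timeseries(blank, fb)
  fr <- file.path(out_dir, sprintf("%s_regime.yaml", scenario_id))
  write_regime(scn$regime, fr)
  manifest <- list(
    scenario_id = scenario_id, seed = seed, replicates = replicates,
    sampling_interval_min = sampling_interval_min,
    tool = paste0("oxyclock ", as.character(utils::packageVersion("oxyclock"))),
    created = format(Sys.time(), tz = "UTC"),
    files = c(files, fb, fr)
  )
  yaml::write_yaml(manifest, file.path(out_dir, sprintf("%s_manifest.yaml", scenario_id)))
  invisible(manifest)
}

#' Per-replicate period estimates for one scenario
#'
#' The full analysis chain on simulated (or re-read) traces: blank
#' correction, segmentation into the LD entrainment block and the LL free
#' run, linear detrend, Hann-windowed zero-padded periodogram and
#' dominant-period extraction in the circadian band -- one row per
#' (segment, replicate).
#'
#' @param scn A [scenario()] or packaged scenario id.
#' @param seed Root seed for trace generation.
#' @param band_h Period search band (h).
#' @param pad_factor,window,detrend_method Estimator settings (see
#'   [estimate_period()]).
#' @param skip_transition_h Hours dropped after each mode switch (see
#'   [segment()]).
#' @param use_blank Apply blank correction (default `TRUE`).
#' @param method `"fft"` or `"lsq-scan"`.
#' @param sampling_interval_min Sampling interval (minutes).
#' @return A tibble: `scenario`, `organism`, `spectrum`, `irradiance`,
#'   `segment`, `mode`, `replicate`, `tau_h`, `edge_flag`,
#'   `low_power_flag`.
#' @export
scenario_periods <- function(scn, seed = 1, band_h = c(19, 28),
                             pad_factor = 16, window = "hann",
                             detrend_method = "linear",
                             skip_transition_h = 0, use_blank = TRUE,
                             method = c("fft", "lsq-scan"),
                             sampling_interval_min = 5) {
  if (is.character(scn)) scn <- get_scenario(scn)
  stopifnot(inherits(scn, "scenario"))
  method <- match.arg(method)
  blank <- simulate_blank_series(scn, sampling_interval_min, seed)
  meta <- scenario_table()
  meta <- meta[meta$id == scn$id, ]
  rows <- list()
  for (r in seq_len(scn$n_replicates)) {
    ts <- simulate_oxygen_series(scn, r, sampling_interval_min, seed)
    if (use_blank) ts <- blank_correct(ts, blank)
    segs <- segment(ts, scn$regime, skip_transition_h = skip_transition_h)
    for (lab in names(segs)) {
      est <- if (method == "fft") {
        estimate_period(segs[[lab]], band_h = band_h, pad_factor = pad_factor,
                        window = window, detrend_method = detrend_method)
      } else {
        lsq_period_scan(segs[[lab]], band_h = band_h,
                        detrend_method = detrend_method)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scenario = scn$id,
        organism = if (nrow(meta)) meta$organism else scn$organism,
        spectrum = if (nrow(meta)) meta$spectrum else scn$regime$spectrum[1],
        irradiance = if (nrow(meta)) meta$irradiance else scn$regime$irradiance[1],
        segment = lab, mode = sub("-.*", "", lab), replicate = r,
        tau_h = est$tau_h, edge_flag = est$edge_flag,
        low_power_flag = est$low_power_flag
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Study-wide period summary table
#'
#' Runs [scenario_periods()] over the packaged scenarios and summarises
#' per scenario and light mode as mean +/- sample SD over replicates --
#' the layout in which circadian period results are tabulated (organism,
#' spectrum, intensity, entrained LD period, free-running LL period, N).
#'
#' @param scenario_ids Scenario ids (default: all packaged scenarios).
#' @param seed Root seed.
#' @param ... Passed to [scenario_periods()].
#' @return A tibble with one row per scenario: `scenario`, `organism`,
#'   `spectrum`, `irradiance`, `ld_tau_h`, `ld_sd_h`, `ll_tau_h`,
#'   `ll_sd_h`, `n`.
#' @export
period_summary_table <- function(scenario_ids = scenario_table()$id, seed = 1,
                                 ...) {
  per_rep <- dplyr::bind_rows(lapply(scenario_ids, function(id) {
    scenario_periods(id, seed = seed, ...)
  }))
  agg <- function(df) c(mean = mean(df$tau_h), sd = stats::sd(df$tau_h),
                        n = nrow(df))
  rows <- lapply(split(per_rep, factor(per_rep$scenario, levels = unique(per_rep$scenario))),
                 function(df) {
    ld <- df[df$mode == "LD", ]
    ll <- df[df$mode == "LL", ]
    tibble::tibble(
      scenario = df$scenario[1], organism = df$organism[1],
      spectrum = df$spectrum[1], irradiance = df$irradiance[1],
      ld_tau_h = mean(ld$tau_h), ld_sd_h = stats::sd(ld$tau_h),
      ll_tau_h = mean(ll$tau_h), ll_sd_h = stats::sd(ll$tau_h),
      n = max(df$replicate)
    )
  })
  dplyr::bind_rows(rows)
}

#' End-to-end qPCR relative-expression analysis
#'
#' From a Ct table: pick (or accept) the reference gene, compute
#' delta-delta-Ct relative quantities per target gene with a per-spectrum
#' pre-dawn LD calibrator, and attach per-(gene, condition, spectrum)
#' time-course statistics: one-way ANOVA across clock times on replicate
#' RQs, followed by Tukey HSD compact letters.
#'
#' @param ct A Ct table (see [read_ct_table()]), e.g. from
#'   [simulate_qpcr_ct()].
#' @param targets Target gene names.
#' @param hkg `"auto"` (stability selection among `hkg_candidates`) or a
#'   gene name.
#' @param hkg_candidates Candidates for automatic selection.
#' @param calibrator `"auto"` (the 06:30 LD sample of the same spectrum)
#'   or a `sample_id`.
#' @param base Amplification base in (1, 2].
#' @param alpha Significance level for the letter display.
#' @return A list: `expression` (headline RQ per sample),
#'   `expression_replicates` (per-replicate RQ), `stats` (tibble of gene,
#'   condition, spectrum, clock_time, mean_rq, sd_rq, letter, plus ANOVA
#'   F/p), `hkg` (selection object or name), `calibrators`.
#' @export
qpcr_pipeline <- function(ct, targets = c("CRY1", "CRY2", "PHY"),
                          hkg = "auto",
                          hkg_candidates = c("Actin", "Cyclophilin", "SAM-synthetase"),
                          calibrator = "auto", base = 2, alpha = 0.05) {
  ct <- validate_ct_table(ct)
  selection <- NULL
  if (identical(hkg, "auto")) {
    selection <- select_hkg(ct, hkg_candidates)
    hkg_gene <- selection$gene
  } else {
    hkg_gene <- hkg
  }
  spectra <- unique(ct$spectrum[ct$gene %in% targets])
  expr_mean <- list()
  expr_rep <- list()
  calibrators <- character(0)
  for (gene in targets) {
    for (sp in spectra) {
      sub <- ct[ct$gene %in% c(gene, hkg_gene) & ct$spectrum == sp, ]
      cal <- if (identical(calibrator, "auto")) {
        ids <- unique(sub$sample_id[sub$condition == "LD" & sub$clock_time == "06:30"])
        if (length(ids) == 0) {
          abort_validation(paste0("no 06:30 LD calibrator sample for spectrum ", sp))
        }
        ids[1]
      } else calibrator
      calibrators[paste(gene, sp, sep = "/")] <- cal
      expr_mean[[paste(gene, sp)]] <- ddct(sub, gene, hkg_gene, cal, base, "mean")
      expr_rep[[paste(gene, sp)]] <- ddct(sub, gene, hkg_gene, cal, base, "keep")
    }
  }
  expr_mean <- dplyr::bind_rows(expr_mean)
  expr_rep <- dplyr::bind_rows(expr_rep)

  stats_rows <- list()
  combos <- unique(expr_rep[, c("gene", "condition", "spectrum")])
  for (i in seq_len(nrow(combos))) {
    sub <- expr_rep[expr_rep$gene == combos$gene[i] &
                    expr_rep$condition == combos$condition[i] &
                    expr_rep$spectrum == combos$spectrum[i], ]
    grp <- split(sub$relative_quantity, sub$clock_time)
    anova_res <- one_way_anova(grp, alpha = alpha)
    tukey <- tukey_hsd(grp, alpha = alpha)
    for (tp in names(grp)) {
      stats_rows[[length(stats_rows) + 1L]] <- tibble::tibble(
        gene = combos$gene[i], condition = combos$condition[i],
        spectrum = combos$spectrum[i], clock_time = tp,
        mean_rq = mean(grp[[tp]]), sd_rq = stats::sd(grp[[tp]]),
        letter = tukey$letters[[tp]],
        anova_f = anova_res$statistic, anova_p = anova_res$p_value
      )
    }
  }
  list(expression = expr_mean, expression_replicates = expr_rep,
       stats = dplyr::bind_rows(stats_rows),
       hkg = selection %||% hkg_gene, hkg_gene = hkg_gene,
       calibrators = calibrators, base = base)
}
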