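#' qPCR experimental design and expression ground truth
#'
#' Describes the diel expression experiment: target photoreceptor genes
#' (two cryptochromes, one phytochrome) and candidate housekeeping genes,
#' sampled at five clock times around the 08:00-20:00 light window under
#' LD and LL, each under blue and red light, with triplicate reactions.
#'
#' The default `expression_profiles` encode the qualitative structure of
#' the published diel profiles, on a relative scale where the pre-dawn
#' (06:30) LD sample of each spectrum is 1: CRY genes peak at 16:00 under
#' LD and shift their peak to 12:00 under constant light, with overall
#' levels more than twofold higher under blue than red light; the PHY gene
#' peaks at 16:00 under both conditions, is higher under red light, and
#' under constant red light runs three-fold above its LD levels. The
#' pre-dawn baseline is taken as equal across spectra (the spectral fold
#' difference is light-induced), which keeps those folds visible after
#' delta-delta-Ct normalisation to the per-spectrum 06:30 LD calibrator.
#'
#' @param efficiency Amplification efficiency E per gene (per-cycle
#'   amplification factor in (1, 2]); default 1.9 for all genes, the
#'   dilution-series estimate for these assays.
#' @param ct_sd Gaussian Ct noise SD (cycles) for target genes.
#' @param hkg_ct_sd Named per-housekeeping-gene Ct noise SD (cycles);
#'   Cyclophilin is the most stable by default.
#' @param n_replicates Reactions per (gene, condition, spectrum, time).
#' @return A `qpcr_design` list.
#' @export
qpcr_design <- function(efficiency = 1.9, ct_sd = 0.2,
                        hkg_ct_sd = c(Actin = 0.5, Cyclophilin = 0.15,
                                      "SAM-synthetase" = 0.4),
                        n_replicates = 3) {
  targets <- c("CRY1", "CRY2", "PHY")
  hkgs <- names(hkg_ct_sd)
  if (n_replicates < 2) abort_validation("n_replicates must be >= 2")
  eff <- if (length(efficiency) == 1) stats::setNames(rep(efficiency, length(targets)), targets) else efficiency
  if (any(eff <= 1 | eff > 2)) abort_validation("efficiency must lie in (1, 2]")
  times <- c("06:30", "08:30", "12:00", "16:00", "20:30")
  prof <- function(gene, condition, spectrum, expr) {
    tibble::tibble(gene = gene, condition = condition, spectrum = spectrum,
                   clock_time = times, expression = expr)
  }
  profiles <- dplyr::bind_rows(
    prof("CRY1", "LD", "blue", c(1.0, 3.0, 5.0, 8.0, 3.25)),
    prof("CRY1", "LD", "red",  c(1.0, 1.2, 2.0, 3.2, 1.3)),
    prof("CRY1", "LL", "blue", c(1.0, 3.0, 6.5, 4.0, 2.6)),
    prof("CRY1", "LL", "red",  c(1.0, 1.2, 2.6, 1.6, 1.1)),
    prof("CRY2", "LD", "blue", c(1.0, 2.8, 5.2, 7.6, 3.0)),
    prof("CRY2", "LD", "red",  c(1.0, 1.1, 2.0, 3.0, 1.2)),
    prof("CRY2", "LL", "blue", c(1.0, 2.6, 6.0, 3.8, 2.4)),
    prof("CRY2", "LL", "red",  c(1.0, 1.05, 2.4, 1.5, 1.0)),
    prof("PHY",  "LD", "blue", c(1.0, 1.2, 1.6, 2.2, 1.3)),
    prof("PHY",  "LD", "red",  c(1.0, 1.8, 3.0, 6.0, 2.0)),
    prof("PHY",  "LL", "blue", c(1.0, 1.2, 1.6, 2.2, 1.3)),
    prof("PHY",  "LL", "red",  c(3.0, 5.4, 9.0, 18.0, 6.0))
  )
  if (any(profiles$expression <= 0)) {
    abort_validation("expression profiles must be strictly positive")
  }
  structure(
    list(
      target_genes = targets,
      hkg_candidates = hkgs,
      time_points = times,
      conditions = c("LD", "LL"),
      spectra = c("blue", "red"),
      n_replicates = n_replicates,
      efficiency = eff,
      expression_profiles = profiles,
      ct_sd = ct_sd,
      hkg_ct_sd = hkg_ct_sd,
      # Reference Ct of each gene at unit relative expression.
      ct_ref = c(CRY1 = 28, CRY2 = 28.5, PHY = 27.5,
                 stats::setNames(c(19, 20, 21), hkgs))
    ),
    class = "qpcr_design"
  )
}

#' Simulate a qPCR Ct table under a diel expression design
#'
#' Target-gene Cts follow `Ct_ref(gene) - log_E(expression) + eps` with
#' `eps ~ Normal(0, ct_sd)`: an E-fold change in template shifts Ct by one
#' cycle. Housekeeping candidates have constant expression across all
#' samples up to their per-gene Ct noise, so their observed Ct SD ranks
#' their stability.
#'
#' @param design A [qpcr_design()].
#' @param seed Integer root seed.
#' @return A validated Ct table (see [read_ct_table()] for the schema).
#' @export
simulate_qpcr_ct <- function(design = qpcr_design(), seed = 1) {
  stopifnot(inherits(design, "qpcr_design"))
  grid <- tidyr::expand_grid(
    condition = design$conditions,
    spectrum = design$spectra,
    clock_time = design$time_points,
    replicate = seq_len(design$n_replicates)
  )
  grid$sample_id <- paste(grid$condition, grid$spectrum, grid$clock_time, sep = "_")

  rows <- list()
  for (gene in design$target_genes) {
    g <- dplyr::left_join(
      grid,
      design$expression_profiles[design$expression_profiles$gene == gene, ],
      by = c("condition", "spectrum", "clock_time")
    )
    if (anyNA(g$expression)) {
      abort_validation(paste("missing expression profile entries for", gene))
    }
    e <- design$efficiency[[gene]]
    ct <- design$ct_ref[[gene]] - log(g$expression, base = e)
    if (design$ct_sd > 0) {
      set.seed(derive_seed(seed, "qpcr", gene))
      ct <- ct + stats::rnorm(length(ct), 0, design$ct_sd)
    }
    rows[[gene]] <- tibble::tibble(
      sample_id = g$sample_id, gene = gene, clock_time = g$clock_time,
      condition = g$condition, spectrum = g$spectrum,
      replicate = g$replicate, ct = ct
    )
  }
  for (hkg in design$hkg_candidates) {
    ct <- rep(design$ct_ref[[hkg]], nrow(grid))
    sd_h <- design$hkg_ct_sd[[hkg]]
    if (sd_h > 0) {
      set.seed(derive_seed(seed, "qpcr", hkg))
      ct <- ct + stats::rnorm(length(ct), 0, sd_h)
    }
    rows[[hkg]] <- tibble::tibble(
      sample_id = grid$sample_id, gene = hkg, clock_time = grid$clock_time,
      condition = grid$condition, spectrum = grid$spectrum,
      replicate = grid$replicate, ct = ct
    )
  }
  validate_ct_table(dplyr::bind_rows(rows))
}
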