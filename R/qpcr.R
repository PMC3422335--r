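#' Amplification efficiency from a dilution-series slope
#'
#' A standard curve of Ct against log10 template dilution has slope
#' `-1/log10(E)`; the per-cycle amplification factor is therefore
#' `E = 10^(-1/slope)`. A perfectly efficient reaction (doubling per
#' cycle) has slope -3.3219 and E = 2.
#'
#' @param slope Standard-curve slope (cycles per log10 dilution, < 0).
#' @return The efficiency E.
#' @export
efficiency_from_slope <- function(slope) {
  if (!is_scalar_number(slope) || slope >= 0) {
    abort_validation("standard-curve slope must be a negative number")
  }
  10^(-1 / slope)
}

#' Rank housekeeping-gene candidates by Ct stability
#'
#' A good reference gene has constant expression -- hence constant Ct --
#' across all samples and conditions. Candidates are ranked by the SD (or
#' coefficient of variation) of their Ct values over the whole table; the
#' most stable candidate is selected. Exact ties resolve to the
#' lexicographically first gene and are flagged.
#'
#' @param ct A Ct table (see [read_ct_table()]).
#' @param candidates Candidate gene names; each must appear in >= 2
#'   samples.
#' @param measure `"sd"` (default) or `"cv"`.
#' @return An `hkg_selection`: list with `gene` (the winner), `ranking`
#'   (tibble of gene, n, mean_ct, stability), `measure`, `tie`.
#' @export
select_hkg <- function(ct, candidates, measure = c("sd", "cv")) {
  ct <- validate_ct_table(ct)
  measure <- match.arg(measure)
  missing <- setdiff(candidates, unique(ct$gene))
  if (length(missing)) {
    abort_validation(paste("candidate gene(s) absent from the Ct table:",
                           paste(missing, collapse = ", ")))
  }
  ranking <- dplyr::bind_rows(lapply(candidates, function(g) {
    cts <- ct$ct[ct$gene == g]
    if (length(unique(ct$sample_id[ct$gene == g])) < 2) {
      abort_validation(paste0("candidate ", g, " present in fewer than 2 samples"))
    }
    s <- stats::sd(cts)
    tibble::tibble(gene = g, n = length(cts), mean_ct = mean(cts),
                   stability = if (measure == "cv") s / mean(cts) else s)
  }))
  ranking <- ranking[order(ranking$stability, ranking$gene), ]
  tie <- nrow(ranking) > 1 && ranking$stability[2] == ranking$stability[1]
  structure(
    list(gene = ranking$gene[1], ranking = ranking, measure = measure,
         tie = tie),
    class = "hkg_selection"
  )
}

#' @export
print.hkg_selection <- function(x, ...) {
  cat(sprintf("<hkg_selection> %s (by Ct %s)%s\n", x$gene, x$measure,
              if (x$tie) " [tie, lexicographic]" else ""))
  print(x$ranking)
  invisible(x)
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each sample, `dCt = Ct_target - Ct_hkg`; relative quantity against
#' the calibrator sample is `base^-(dCt_sample - dCt_calibrator)`. The
#' base is the amplification efficiency: 2 for the textbook
#' 2^-ddCt method, or the measured assay efficiency (e.g. 1.9).
#'
#' Replicate reactions are handled by averaging Ct within each
#' `(sample_id, gene)` before forming dCt (`replicates = "mean"`, the
#' headline quantity). `replicates = "keep"` instead computes one RQ per
#' replicate, pairing target and reference Cts by replicate number and
#' using the calibrator's mean dCt -- that is what per-time-point group
#' statistics run on. The two conventions differ whenever Ct noise is
#' non-zero; both are exposed deliberately.
#'
#' @param ct A Ct table (see [read_ct_table()]).
#' @param target Target gene name.
#' @param hkg Reference (housekeeping) gene name.
#' @param calibrator `sample_id` of the calibrator; its relative quantity
#'   is exactly 1.
#' @param base Amplification base in (1, 2]; default 2.
#' @param replicates `"mean"` or `"keep"` (see Details).
#' @return An expression tibble with columns `sample_id`, `gene`,
#'   `clock_time`, `condition`, `spectrum`, (`replicate`,)
#'   `relative_quantity`, `hkg_used`, `calibrator_used`, `base_used`.
#' @export
ddct <- function(ct, target, hkg, calibrator, base = 2,
                 replicates = c("mean", "keep")) {
  ct <- validate_ct_table(ct)
  replicates <- match.arg(replicates)
  if (!is_scalar_number(base) || base <= 1 || base > 2) {
    abort_validation("base must lie in (1, 2]")
  }
  tgt <- ct[ct$gene == target, ]
  ref <- ct[ct$gene == hkg, ]
  if (nrow(tgt) == 0) abort_validation(paste("target gene not in table:", target))
  if (nrow(ref) == 0) abort_validation(paste("reference gene not in table:", hkg))
  no_ref <- setdiff(unique(tgt$sample_id), unique(ref$sample_id))
  if (length(no_ref)) {
    abort_validation(paste("samples missing reference-gene Cts:",
                           paste(no_ref, collapse = ", ")))
  }
  if (!calibrator %in% tgt$sample_id) {
    abort_validation(paste("calibrator sample not in table:", calibrator))
  }
  mean_ct <- function(df) {
    agg <- stats::aggregate(ct ~ sample_id + clock_time + condition + spectrum,
                            data = as.data.frame(df), FUN = mean)
    tibble::as_tibble(agg)
  }
  tgt_m <- mean_ct(tgt)
  ref_m <- mean_ct(ref)
  dct_m <- tgt_m$ct - ref_m$ct[match(tgt_m$sample_id, ref_m$sample_id)]
  dct_cal <- dct_m[match(calibrator, tgt_m$sample_id)]
  if (replicates == "mean") {
    out <- tgt_m
    out$relative_quantity <- base^(-(dct_m - dct_cal))
  } else {
    key <- paste(ref$sample_id, ref$replicate)
    ref_ct <- ref$ct[match(paste(tgt$sample_id, tgt$replicate), key)]
    if (anyNA(ref_ct)) {
      abort_validation("replicate-paired ddCt requires matching replicate numbers for target and reference")
    }
    out <- tgt[, c("sample_id", "clock_time", "condition", "spectrum", "replicate")]
    out$relative_quantity <- base^(-((tgt$ct - ref_ct) - dct_cal))
  }
  out$gene <- target
  out$hkg_used <- hkg
  out$calibrator_used <- calibrator
  out$base_used <- base
  dplyr::relocate(out, "gene", .after = "sample_id")
}
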