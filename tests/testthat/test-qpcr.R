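test_that("amplification efficiency follows 10^(-1/slope)", {
  expect_equal(efficiency_from_slope(-3.321928), 2, tolerance = 1e-6)
  expect_equal(efficiency_from_slope(-3.5865), 1.9, tolerance = 1e-3)
  expect_error(efficiency_from_slope(1), "negative")
  expect_error(efficiency_from_slope(0), "negative")
})

test_that("delta-delta-Ct reproduces the worked fold-change identities", {
  ct <- tiny_ct_table()  # target 24 vs 26, reference 20 vs 20
  rq <- ddct(ct, "TGT", "HKG", calibrator = "cal", base = 2)
  expect_equal(rq$relative_quantity[rq$sample_id == "cal"], 1)
  expect_equal(rq$relative_quantity[rq$sample_id == "s1"], 4)  # ddCt = -2
  rq19 <- ddct(ct, "TGT", "HKG", calibrator = "cal", base = 1.9)
  expect_equal(rq19$relative_quantity[rq19$sample_id == "s1"], 1.9^2)
  expect_error(ddct(ct, "TGT", "HKG", calibrator = "nope", base = 2),
               "calibrator")
  expect_error(ddct(ct, "TGT", "HKG", calibrator = "cal", base = 3), "base")
  expect_error(ddct(ct[ct$gene == "TGT", ], "TGT", "HKG", "cal", 2),
               "reference gene")
})

test_that("relative quantities are invariant to a global Ct shift", {
  ct <- simulate_qpcr_ct(qpcr_design(), seed = 6)
  rq1 <- ddct(ct, "CRY1", "Cyclophilin", "LD_blue_06:30", base = 1.9)
  shifted <- ct
  shifted$ct <- shifted$ct + 3.7
  rq2 <- ddct(shifted, "CRY1", "Cyclophilin", "LD_blue_06:30", base = 1.9)
  expect_equal(rq2$relative_quantity, rq1$relative_quantity, tolerance = 1e-9)
})

test_that("with zero Ct noise the generator's expression profiles round trip exactly", {
  design <- qpcr_design(ct_sd = 0,
                        hkg_ct_sd = c(Actin = 0, Cyclophilin = 0,
                                      "SAM-synthetase" = 0))
  ct <- simulate_qpcr_ct(design, seed = 1)
  for (gene in design$target_genes) {
    for (sp in design$spectra) {
      sub <- ct[ct$spectrum == sp & ct$gene %in% c(gene, "Cyclophilin"), ]
      rq <- ddct(sub, gene, "Cyclophilin",
                 calibrator = paste0("LD_", sp, "_06:30"),
                 base = design$efficiency[[gene]])
      prof <- design$expression_profiles
      prof <- prof[prof$gene == gene & prof$spectrum == sp, ]
      key <- paste(rq$condition, rq$clock_time)
      expect_equal(rq$relative_quantity,
                   prof$expression[match(key, paste(prof$condition, prof$clock_time))],
                   tolerance = 1e-9)
    }
  }
})

test_that("halving expression at base 2 raises Ct by exactly one cycle", {
  design <- qpcr_design(efficiency = 2, ct_sd = 0)
  design$expression_profiles$expression[
    design$expression_profiles$gene == "CRY1"] <- 2
  ct_hi <- simulate_qpcr_ct(design, seed = 1)
  design$expression_profiles$expression[
    design$expression_profiles$gene == "CRY1"] <- 1
  ct_lo <- simulate_qpcr_ct(design, seed = 1)
  expect_equal(ct_lo$ct[ct_lo$gene == "CRY1"] - ct_hi$ct[ct_hi$gene == "CRY1"],
               rep(1, sum(ct_lo$gene == "CRY1")), tolerance = 1e-12)
})

test_that("reference-gene selection ranks candidates by Ct stability", {
  ct <- simulate_qpcr_ct(qpcr_design(), seed = 2)
  sel <- select_hkg(ct, c("Actin", "Cyclophilin", "SAM-synthetase"))
  expect_equal(nrow(sel$ranking), 3L)
  expect_true(all(diff(sel$ranking$stability) >= 0))
  expect_error(select_hkg(ct, c("Cyclophilin", "GAPDH")), "absent")

  # A literally constant candidate always wins.
  const <- ct
  const$ct[const$gene == "Actin"] <- 21
  expect_identical(select_hkg(const, c("Actin", "Cyclophilin"))$gene, "Actin")

  # Exact tie resolves lexicographically and is flagged.
  tied <- ct[ct$gene %in% c("Actin", "Cyclophilin"), ]
  tied$ct[tied$gene == "Actin"] <- 21
  tied$ct[tied$gene == "Cyclophilin"] <- 23
  sel_tie <- select_hkg(tied, c("Actin", "Cyclophilin"))
  expect_identical(sel_tie$gene, "Actin")
  expect_true(sel_tie$tie)
})

test_that("the most stable simulated housekeeping gene is selected almost always", {
  wins <- vapply(seq_len(100), function(s) {
    ct <- simulate_qpcr_ct(qpcr_design(), seed = s)
    select_hkg(ct, c("Actin", "Cyclophilin", "SAM-synthetase"))$gene
  }, character(1))
  expect_gte(mean(wins == "Cyclophilin"), 0.95)
})

test_that("diel expression peaks and spectral folds are recovered end to end", {
  ct <- simulate_qpcr_ct(qpcr_design(), seed = 4)
  res <- qpcr_pipeline(ct, base = 2)
  expect_identical(res$hkg_gene, "Cyclophilin")
  st <- res$stats
  for (gene in c("CRY1", "CRY2")) {
    for (sp in c("blue", "red")) {
      ld <- st[st$gene == gene & st$condition == "LD" & st$spectrum == sp, ]
      ll <- st[st$gene == gene & st$condition == "LL" & st$spectrum == sp, ]
      expect_identical(ld$clock_time[which.max(ld$mean_rq)], "16:00")
      expect_identical(ll$clock_time[which.max(ll$mean_rq)], "12:00")
    }
  }
  # The 06:30 pre-dawn sample is the per-spectrum calibrator, so its RQ is
  # pinned to 1 in both spectra; the twofold blue/red relation concerns
  # CRY expression levels during the light phase, under both conditions.
  for (cond in c("LD", "LL")) {
    day <- st$gene %in% c("CRY1", "CRY2") & st$condition == cond &
      st$clock_time != "06:30"
    expect_gte(mean(st$mean_rq[day & st$spectrum == "blue"]) /
               mean(st$mean_rq[day & st$spectrum == "red"]), 2)
  }
  phy <- st[st$gene == "PHY", ]
  expect_identical(phy$clock_time[phy$condition == "LD" & phy$spectrum == "red"][
    which.max(phy$mean_rq[phy$condition == "LD" & phy$spectrum == "red"])], "16:00")
  ratio <- mean(phy$mean_rq[phy$condition == "LL" & phy$spectrum == "red"]) /
    mean(phy$mean_rq[phy$condition == "LD" & phy$spectrum == "red"])
  expect_equal(ratio, 3, tolerance = 0.15 * 3)
})
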