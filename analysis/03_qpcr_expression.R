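#!/usr/bin/env Rscript

# Step 3: diel photoreceptor gene expression. Simulate the qPCR Ct table
# for CRY1/CRY2/PHY plus housekeeping candidates under LD and LL in blue
# and red light, rank the housekeeping genes by Ct stability, compute
# delta-delta-Ct relative expression against the pre-dawn LD calibrator,
# and attach per-time-course ANOVA + Tukey compact letters.

library(oxyclock)

seed <- 1
dir.create("results", showWarnings = FALSE)

ct <- simulate_qpcr_ct(qpcr_design(), seed = seed)
write_ct_table(ct, "results/qpcr_ct.csv")

res <- qpcr_pipeline(ct, base = 2)

cat("Housekeeping-gene stability ranking (SD of Ct across all samples):\n")
print(as.data.frame(res$hkg$ranking), digits = 3)
cat("selected:", res$hkg_gene, "\n\n")
utils::write.csv(res$hkg$ranking, "results/hkg_ranking.csv", row.names = FALSE)

utils::write.csv(res$expression, "results/qpcr_expression.csv", row.names = FALSE)
utils::write.csv(res$stats, "results/qpcr_stats.csv", row.names = FALSE)

cat("Peak expression time per (gene, condition, spectrum):\n")
st <- res$stats
peaks <- do.call(rbind, lapply(split(st, st[c("gene", "condition", "spectrum")]),
  function(df) {
    data.frame(gene = df$gene[1], condition = df$condition[1],
               spectrum = df$spectrum[1],
               peak_time = df$clock_time[which.max(df$mean_rq)],
               peak_rq = max(df$mean_rq),
               letters = paste(df$letter, collapse = "/"))
  }))
print(peaks[order(peaks$gene, peaks$condition, peaks$spectrum), ],
      row.names = FALSE, digits = 3)

day <- st$gene %in% c("CRY1", "CRY2") & st$clock_time != "06:30"
for (cond in c("LD", "LL")) {
  r <- mean(st$mean_rq[day & st$condition == cond & st$spectrum == "blue"]) /
       mean(st$mean_rq[day & st$condition == cond & st$spectrum == "red"])
  cat(sprintf("CRY light-phase blue/red fold (%s): %.2f\n", cond, r))
}
phy_ll <- mean(st$mean_rq[st$gene == "PHY" & st$condition == "LL" & st$spectrum == "red"])
phy_ld <- mean(st$mean_rq[st$gene == "PHY" & st$condition == "LD" & st$spectrum == "red"])
cat(sprintf("PHY red LL/LD fold: %.2f\n", phy_ll / phy_ld))
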