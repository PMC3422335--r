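#!/usr/bin/env Rscript

# Step 1: generate the raw material for the workflow -- replicate optode
# oxygen-evolution traces plus medium-only blank channels for each
# packaged light scenario, written as plain CSV with a regime config and
# a run manifest so any file can be regenerated bit-identically.

library(oxyclock)

seed <- 1
out_root <- file.path("results", "simulated")

for (id in scenario_table()$id) {
  m <- write_scenario_run(id, file.path(out_root, id), seed = seed)
  cat(sprintf("%-4s: wrote %d files (%d replicates + blank + regime + manifest)\n",
              id, length(m$files) + 1, m$replicates))
}

# Spot-check that a written trace survives the round trip intact.
reg <- read_regime(file.path(out_root, "S1", "S1_regime.yaml"))
ts <- read_timeseries(file.path(out_root, "S1", "S1_rep1.csv"), regime = reg)
scn <- get_scenario("S1")
orig <- simulate_oxygen_series(scn, 1, seed = seed)
stopifnot(max(abs(ts$values - orig$values)) < 1e-12)
cat(sprintf("\nround trip OK: S1 rep1, %d points over %.0f h (LD 72 h + LL 96 h)\n",
            length(ts), max(ts$time_h)))
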