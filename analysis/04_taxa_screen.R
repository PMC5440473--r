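#!/usr/bin/env Rscript
# Methane-cycler guild screen demonstrated on synthetic archaeal
# communities emulating the spring samples: combined methanogen + ANME
# target fractions span 0.40-0.90 of archaeal reads, the band observed in
# hyperalkaline spring fluids, and the screen recovers them to multinomial
# precision.

suppressPackageStartupMessages({
  library(serpenergy)
  library(dplyr)
})

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
seed <- 20140201  # field campaign date as a memorable fixed seed

sim <- run_simulate(seed = seed)
scr <- run_screen(sim$taxonomy$table, out_dir = out_dir)

cat("Per-sample guild fractions (synthetic spring-like communities):\n")
print(as.data.frame(scr$screen$fractions), digits = 3)

truth <- sim$taxonomy$truth
est <- scr$screen$fractions[match(truth$sample_id, scr$screen$fractions$sample_id), ]
cat("\nTarget vs screened combined methanogen+ANME fraction:\n")
for (i in seq_len(nrow(truth))) {
  cat(sprintf("  %s  target %.3f  screened %.3f\n", truth$sample_id[i],
              truth$methanogen[i] + truth$anme[i], est$methane_cycler[i]))
}
cat(sprintf("\nScreened range: %.1f%% - %.1f%% of archaeal reads (targets 40-90%%).\n",
            100 * min(est$methane_cycler), 100 * max(est$methane_cycler)))
cat("The Methanoperedens (ANME-2d) lineage inside Methanosarcinales is\n")
cat("counted as ANME, not methanogen - the override the guild lists encode.\n")
cat("Wrote guild_fractions.csv, guild_summary.csv, matched_lineages.json\n")
cat("under", out_dir, "\n")
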