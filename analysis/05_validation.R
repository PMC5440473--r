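#!/usr/bin/env Rscript
# Cross-validation of the computational machinery: solver vs closed-form
# speciation oracle on random fluids, analytically solved fixtures, and
# multinomial recovery of guild fractions, summarised to JSON.

suppressPackageStartupMessages(library(serpenergy))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
seed <- 20140201

# solver vs oracle on 100 simulated fluids
worst <- 0
for (k in seq_len(100)) {
  s <- simulate_fluid_table(fluid_sim_params(n_spring = 1, n_background = 1,
                                             seed = seed + k))$samples[1, ]
  a <- speciate(s)
  b <- speciation_oracle(s)
  m <- merge(a$species, b$species, by = "species")
  keep <- m$activity.y > 0
  worst <- max(worst, max(abs(m$activity.x[keep] - m$activity.y[keep]) /
                            m$activity.y[keep]))
}
cat(sprintf("solver vs oracle, 100 random fluids: max rel. activity diff %.2e\n",
            worst))

# analytically solved fixtures
fix_worst <- 0
for (cs in list(c(11.54, 299.25, 227, 0.01), c(8.42, 298.15, 597, 0.005))) {
  kc <- known_speciation_case(cs[1], cs[2], cs[3], cs[4])
  sp <- speciate(kc$sample, kc$filler_na_cl_mM)
  m <- merge(sp$species, kc$expected, by = "species")
  keep <- m$molality.y > 0
  fix_worst <- max(fix_worst, max(abs(m$activity.x[keep] - m$activity.y[keep]) /
                                    m$activity.y[keep]))
}
cat(sprintf("analytic fixtures: max rel. activity diff %.2e\n", fix_worst))

# guild-fraction recovery, 1000 replicates at 10,000 reads
n_rep <- 1000; n_reads <- 10000
set.seed(seed)
f_mg <- runif(n_rep, 0.1, 0.6); f_an <- runif(n_rep, 0.05, 0.3)
targets <- tibble::tibble(sample_id = sprintf("r%04d", seq_len(n_rep)),
                          methanogen = f_mg, anme = f_an)
sim <- simulate_taxonomy_table(tax_sim_params(targets, n_reads = n_reads,
                                              seed = seed + 1))
fr <- screen_methane_cyclers(sim$table)$fractions
fr <- fr[match(targets$sample_id, fr$sample_id), ]
band <- function(f) 4 * sqrt(f * (1 - f) / n_reads)
hit <- abs(fr$methanogen - f_mg) <= band(f_mg) & abs(fr$anme - f_an) <= band(f_an)
cat(sprintf("guild recovery: %.1f%% of %d replicates inside the 4-sigma band\n",
            100 * mean(hit), n_rep))

jsonlite::write_json(
  list(speciation_oracle_max_rel_diff = worst,
       analytic_fixture_max_rel_diff = fix_worst,
       guild_recovery_within_4sigma = mean(hit),
       n_fluids = 100, n_replicates = n_rep, n_reads = n_reads, seed = seed),
  file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("Wrote", file.path(out_dir, "validation.json"), "\n")
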