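#!/usr/bin/env Rscript
# Free-energy yields per liter at the three hyperalkaline springs over the
# scenario grid (acetate at 1%/10% of DOC, O2 at 0.1%/1% air saturation,
# nitrate from measured NOx; sulfate-AOM reported as skipped because
# sulfate was not measured), with per-site pathway rankings, a sensitivity
# note on the orderings, and a grouped bar chart.

suppressPackageStartupMessages({
  library(serpenergy)
  library(dplyr)
})

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

sites <- load_seo_fixture()
res <- withCallingHandlers(
  run_energetics(sites, out_dir = out_dir),
  warning = function(w) {
    message("note: ", conditionMessage(w))
    invokeRestart("muffleWarning")
  })

g <- res$energetics
cat("Energy densities (J per L of fluid), three springs x seven cells:\n")
print(as.data.frame(g %>%
  filter(status == "ok") %>%
  select(site_id, cell, limiting_species, extent_umol_L, dG_kJ_mol, energy_J_L)),
  digits = 3)

e <- function(site, cell) g$energy_J_L[g$site_id == site & g$cell == cell]
cat("\nOrderings:\n")
cat(sprintf("  Q. Danta: MG %.3f > AM(10) %.4f and AM(1) %.5f J/L\n",
            e("Q. Danta", "MG"), e("Q. Danta", "AM(10)"), e("Q. Danta", "AM(1)")))
cat(sprintf("  Spring 8: AM(10) %.3f > MG %.3f J/L (DOM-assumption dependent)\n",
            e("Spring 8", "AM(10)"), e("Spring 8", "MG")))
cat(sprintf("  Spring 9: MG %.3f > AM(10) %.3f J/L\n",
            e("Spring 9", "MG"), e("Spring 9", "AM(10)")))
cat("  Nitrate-AOM is electron-acceptor limited everywhere (extent <= NOx/4\n")
cat("  <= 0.2 umol/L, orders of magnitude below CH4 availability).\n")

cat("\nSensitivity note on AOM vs methanogenesis:\n")
cat(sprintf(
  "  At Springs 8 and 9, nitrate-AOM (%.3f, %.3f J/L) sits below both the MG\n",
  e("Spring 8", "NO3"), e("Spring 9", "NO3")))
cat("  and the 10%-acetate AM yields. At Q. Danta, however, nitrate-AOM\n")
cat(sprintf(
  "  (%.3f J/L) exceeds the acetoclastic yields (%.4f / %.5f J/L): DOC there\n",
  e("Q. Danta", "NO3"), e("Q. Danta", "AM(10)"), e("Q. Danta", "AM(1)")))
cat("  is only 5.6 uM while NOx is 0.8 uM, so the huge per-mole energy of\n")
cat("  nitrate-AOM (~ -570 kJ/mol) outweighs its tiny extent. The same holds\n")
cat("  against the 1%-acetate bars at all three springs. The AOM-below-\n")
cat("  methanogenesis ordering is therefore robust for Springs 8 and 9 but\n")
cat("  assumption-dependent at Q. Danta.\n")

p <- plot_energy_density(g)
ggplot2::ggsave(file.path(out_dir, "energy_density.png"), p,
                width = 9, height = 4, dpi = 150)
cat("\nWrote energy_density.csv, pathway_rankings.csv, speciation.csv,\n")
cat("energy_density.png under", out_dir, "\n")
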