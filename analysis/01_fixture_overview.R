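#!/usr/bin/env Rscript
# Field-data overview: load the packaged nine-site fluid-chemistry table,
# validate it, and tabulate the spring vs background contrasts (pH, redox,
# CH4, H2, DIC, DOC) that motivate the bioenergetics calculations.

suppressPackageStartupMessages({
  library(serpenergy)
  library(dplyr)
})

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

sites <- load_seo_fixture()
stopifnot(nrow(validate_sites(sites)) == 0)

fields <- c("pH", "orp_mV", "temperature_C", "ch4_uM", "h2_uM",
            "dic_uM", "doc_uM", "nox_uM")
summaries <- bind_rows(lapply(fields, function(f) {
  bind_rows(
    summarize_sites(sites, f, site_type = "spring"),
    summarize_sites(sites, f, site_type = c("river", "well")))
}))
readr::write_csv(summaries, file.path(out_dir, "site_summaries.csv"))

cat("Nine sites (3 hyperalkaline springs, 3 rivers, 3 wells), all valid.\n\n")
cat("Springs vs background (min-max over non-missing values):\n")
for (f in fields) {
  sp <- summaries[summaries$field == f & summaries$predicate == "spring", ]
  bg <- summaries[summaries$field == f & summaries$predicate != "spring", ]
  cat(sprintf("  %-14s springs %8.4g - %8.4g   background %8.4g - %8.4g\n",
              f, sp$min, sp$max, bg$min, bg$max))
}
cat("\nThe springs are hyperalkaline (pH 11.54-11.59), strongly reducing\n")
cat("(ORP -348 to -251 mV), methane- and hydrogen-rich (CH4 145-912 uM,\n")
cat("H2 10.9-53.1 uM) yet DIC-poor relative to background (126-254 vs\n")
cat("418-748 uM) - the serpentinization fingerprint the energetics builds on.\n")
cat("Wrote", file.path(out_dir, "site_summaries.csv"), "\n")
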