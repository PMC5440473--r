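# Shared helpers: tiny in-code fixtures for reader tests and a minimal
# valid site row for property checks.

write_tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

minimal_site <- function(site_id = "S1", site_type = "spring",
                         temperature_C = 25, pH = 11, dic_uM = 200,
                         doc_uM = 40, ch4_uM = 500, h2_uM = 30,
                         nox_uM = 0.5, no2_uM = 0, nh4_uM = 1, po4_uM = 0.2) {
  tibble::tibble(
    site_id = site_id, site_type = site_type, temperature_C = temperature_C,
    pH = pH, conductivity_uS_cm = 500, tds_ppm = NA_real_,
    salinity_ppm = NA_real_, orp_mV = -300, doc_uM = doc_uM, dic_uM = dic_uM,
    d13C_CO2_permil = NA_real_, tdn_uM = NA_real_, nox_uM = nox_uM,
    no2_uM = no2_uM, nh4_uM = nh4_uM, don_uM = NA_real_, po4_uM = po4_uM,
    tdp_uM = NA_real_, ch4_uM = ch4_uM, d13C_CH4_permil = NA_real_,
    h2_uM = h2_uM, d18O_permil = NA_real_, d2H_permil = NA_real_,
    so4_uM = NA_real_
  )
}

# fluid with prescribed activities, for exercising the dG engine directly
fake_fluid <- function(activities, pH = 7, T_K = 298.15, site_id = "fake") {
  structure(list(
    site_id = site_id, pH = pH, temperature_K = T_K,
    ionic_strength_molal = 0, iterations = 1L, residual = 0,
    species = tibble::tibble(
      species = names(activities), charge = 0L,
      molality = unname(activities), gamma = 1,
      activity = unname(activities), assumed = FALSE)
  ), class = "speciated_fluid")
}
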