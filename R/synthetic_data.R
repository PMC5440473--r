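# Ground-truthed synthetic data emulating the study system: hyperalkaline
# spring vs background endmember fluid chemistry, and classified 16S
# taxonomy tables with known guild fractions. Concentrations draw lognormal
# noise (positive, spanning orders of magnitude between endmembers); pH and
# temperature draw normal noise. One integer seed controls every draw;
# sub-stages derive their own seeds from it by fixed small offsets so
# individual stages are independently reproducible.

#' Endmember parameters for the fluid simulator
#'
#' Defaults encode the study conditions: hyperalkaline springs
#' (pH ~ 11.5, reducing, CH4 hundreds of uM, H2 tens of uM, DIC ~ 200 uM,
#' DOC tens of uM) against circumneutral background surface/ground water
#' (pH ~ 8.2, oxidizing, CH4 ~ 0.3 uM, DIC ~ 550 uM).
#'
#' @param n_spring,n_background Number of sites of each type.
#' @param spring,background Named lists of endmember settings; each analyte
#'   entry is `c(mean, cv)` (lognormal, cv = coefficient of variation)
#'   except `pH`, `temperature_C` and `orp_mV` which are `c(mean, sd)`
#'   (normal).
#' @param seed Integer seed.
#' @return List of class `fluid_sim_params`.
#' @export
fluid_sim_params <- function(n_spring = 3, n_background = 6,
                             spring = NULL, background = NULL, seed = 1L) {
  def_spring <- list(
    pH = c(11.5, 0.1), temperature_C = c(27.5, 1.5), orp_mV = c(-300, 50),
    conductivity_uS_cm = c(520, 0.1), doc_uM = c(30, 0.8),
    dic_uM = c(200, 0.25), tdn_uM = c(4, 0.8), nox_uM = c(0.4, 0.7),
    no2_uM = c(0.02, 0.5), nh4_uM = c(1.2, 0.5), po4_uM = c(0.2, 0.5),
    tdp_uM = c(0.1, 0.3), ch4_uM = c(500, 0.8), h2_uM = c(30, 0.7)
  )
  def_background <- list(
    pH = c(8.2, 0.4), temperature_C = c(27, 2.5), orp_mV = c(80, 30),
    conductivity_uS_cm = c(580, 0.2), doc_uM = c(50, 0.6),
    dic_uM = c(550, 0.2), tdn_uM = c(10, 1.0), nox_uM = c(5, 1.2),
    no2_uM = c(0.05, 0.5), nh4_uM = c(1, 0.8), po4_uM = c(1.8, 0.4),
    tdp_uM = c(0.4, 0.5), ch4_uM = c(0.3, 1.0), h2_uM = c(1.5, 1.2)
  )
  spring <- utils::modifyList(def_spring, spring %||% list())
  background <- utils::modifyList(def_background, background %||% list())
  for (em in list(spring, background)) {
    if (em$pH[1] < 6 || em$pH[1] > 12.5) abort("endmember mean pH outside 6-12.5")
    for (nm in names(em)) {
      if (em[[nm]][2] < 0) abort(sprintf("negative dispersion for %s", nm))
    }
  }
  structure(list(n_spring = n_spring, n_background = n_background,
                 spring = spring, background = background,
                 seed = as.integer(seed)),
            class = "fluid_sim_params")
}

draw_endmember <- function(em, n, type_label, id_prefix) {
  rln <- function(mean, cv) {
    if (mean <= 0) return(rep(0, n))
    sdlog <- sqrt(log(1 + cv^2))
    rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  }
  tibble::tibble(
    site_id = sprintf("%s%02d", id_prefix, seq_len(n)),
    site_type = type_label,
    temperature_C = pmin(pmax(rnorm(n, em$temperature_C[1], em$temperature_C[2]), 15), 40),
    pH = pmin(pmax(rnorm(n, em$pH[1], em$pH[2]), 1), 13.5),
    conductivity_uS_cm = rln(em$conductivity_uS_cm[1], em$conductivity_uS_cm[2]),
    tds_ppm = NA_real_, salinity_ppm = NA_real_,
    orp_mV = rnorm(n, em$orp_mV[1], em$orp_mV[2]),
    doc_uM = rln(em$doc_uM[1], em$doc_uM[2]),
    dic_uM = rln(em$dic_uM[1], em$dic_uM[2]),
    d13C_CO2_permil = NA_real_,
    tdn_uM = rln(em$tdn_uM[1], em$tdn_uM[2]),
    nox_uM = rln(em$nox_uM[1], em$nox_uM[2]),
    no2_uM = rln(em$no2_uM[1], em$no2_uM[2]),
    nh4_uM = rln(em$nh4_uM[1], em$nh4_uM[2]),
    don_uM = NA_real_,
    po4_uM = rln(em$po4_uM[1], em$po4_uM[2]),
    tdp_uM = rln(em$tdp_uM[1], em$tdp_uM[2]),
    ch4_uM = rln(em$ch4_uM[1], em$ch4_uM[2]),
    d13C_CH4_permil = NA_real_,
    h2_uM = rln(em$h2_uM[1], em$h2_uM[2]),
    d18O_permil = NA_real_, d2H_permil = NA_real_,
    so4_uM = NA_real_
  )
}

#' Simulate a fluid-geochemistry table
#'
#' Draws `n_spring` hyperalkaline-spring and `n_background` background
#' sites from the endmember distributions in `p`. NOx is adjusted to be at
#' least NO2 (so derived nitrate is nonnegative). Every generated row
#' passes [validate_sample()]; the same seed yields the identical table.
#'
#' @param p A [fluid_sim_params()].
#' @return List: `samples` (site tibble), `truth` (the endmember settings
#'   used, i.e. `p`).
#' @export
simulate_fluid_table <- function(p = fluid_sim_params()) {
  samples <- withr::with_seed(p$seed, {
    sp <- draw_endmember(p$spring, p$n_spring, "spring", "SYN-SPRING-")
    bg <- draw_endmember(p$background, p$n_background, "river", "SYN-BG-")
    dplyr::bind_rows(sp, bg)
  })
  samples$nox_uM <- pmax(samples$nox_uM, samples$no2_uM)
  samples <- samples[SITE_FIELDS]
  bad <- validate_sites(samples)
  if (nrow(bad) > 0) {
    abort(sprintf("simulated table failed validation: %s",
                  paste(bad$violation, collapse = "; ")))
  }
  list(samples = samples, truth = p)
}

#' Parameters for the taxonomy-table simulator
#'
#' @param targets Data frame with a `sample_id` column and per-guild target
#'   fraction columns (`methanogen`, `anme` for Archaea;
#'   `methanotroph_bacteria`, `methanotroph_nc10` for Bacteria). Fractions
#'   in each row must sum to <= 1; the remainder goes to filler taxa.
#' @param n_reads Reads per sample (> 0).
#' @param n_filler_taxa Number of non-guild filler lineages.
#' @param domain `"Archaea"` or `"Bacteria"`.
#' @param seed Integer seed.
#' @return List of class `tax_sim_params`.
#' @export
tax_sim_params <- function(targets, n_reads = 10000, n_filler_taxa = 15,
                           domain = c("Archaea", "Bacteria"), seed = 1L) {
  domain <- match.arg(domain)
  if (!"sample_id" %in% names(targets)) abort("targets needs a sample_id column")
  guild_cols <- setdiff(names(targets), "sample_id")
  if (length(guild_cols) == 0) abort("targets needs at least one guild column")
  sums <- rowSums(as.matrix(targets[guild_cols]))
  if (any(sums > 1 + 1e-12)) abort("guild fractions must sum to <= 1 per sample")
  if (any(as.matrix(targets[guild_cols]) < 0)) abort("guild fractions must be >= 0")
  if (n_reads <= 0) abort("n_reads must be > 0")
  structure(list(targets = tibble::as_tibble(targets), n_reads = n_reads,
                 n_filler_taxa = n_filler_taxa, domain = domain,
                 seed = as.integer(seed)),
            class = "tax_sim_params")
}

# representative lineages per guild (SILVA/mothur style, 6 ranks)
guild_lineages <- function(domain) {
  if (domain == "Archaea") {
    list(
      methanogen = c(
        "Archaea;Euryarchaeota;Methanobacteria;Methanobacteriales;Methanobacteriaceae;Methanobacterium",
        "Archaea;Euryarchaeota;Methanomicrobia;Methanomicrobiales;Methanoregulaceae;Methanolinea",
        "Archaea;Euryarchaeota;Methanomicrobia;Methanosarcinales;Methanosarcinaceae;Methanosarcina",
        "Archaea;Euryarchaeota;Methanomicrobia;Methanosarcinales;Methanosaetaceae;Methanosaeta"),
      anme = c(
        "Archaea;Euryarchaeota;Methanomicrobia;ANME-1b;ANME-1b_unclassified;ANME-1b_unclassified",
        "Archaea;Euryarchaeota;Methanomicrobia;Methanosarcinales;ANME-2d;Candidatus_Methanoperedens")
    )
  } else {
    list(
      methanotroph_bacteria = c(
        "Bacteria;Proteobacteria;Gammaproteobacteria;Methylococcales;Methylococcaceae;Methylomonas",
        "Bacteria;Proteobacteria;Gammaproteobacteria;Methylococcales;Methylococcaceae;Methylobacter",
        "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Methylocystaceae;Methylocystis"),
      methanotroph_nc10 = c(
        "Bacteria;NC10;NC10_class;NC10_order;NC10_family;Candidatus_Methylomirabilis")
    )
  }
}

filler_lineages <- function(domain, n) {
  if (domain == "Archaea") {
    sprintf("Archaea;Crenarchaeota;Thermoprotei;SyntheticOrder%02d;SyntheticFamily%02d;SyntheticGenus%02d",
            seq_len(n), seq_len(n), seq_len(n))
  } else {
    sprintf("Bacteria;Proteobacteria;Betaproteobacteria;SyntheticOrder%02d;SyntheticFamily%02d;SyntheticGenus%02d",
            seq_len(n), seq_len(n), seq_len(n))
  }
}

#' Simulate a classified taxonomy table with known guild fractions
#'
#' Reads are allocated by a single multinomial draw per sample over guild
#' lineages (target fraction split evenly across that guild's
#' representative lineages) and filler lineages (the remaining fraction).
#' Deterministic for a given seed.
#'
#' @param p A [tax_sim_params()].
#' @return List: `table` (taxonomy tibble consumable by
#'   [screen_methane_cyclers()]), `truth` (target fractions per sample).
#' @export
simulate_taxonomy_table <- function(p) {
  gl <- guild_lineages(p$domain)
  guild_cols <- setdiff(names(p$targets), "sample_id")
  unknown <- setdiff(guild_cols, names(gl))
  if (length(unknown) > 0) {
    abort(sprintf("no %s lineages for guild(s): %s", p$domain,
                  paste(unknown, collapse = ", ")))
  }
  fillers <- filler_lineages(p$domain, p$n_filler_taxa)
  lineages <- c(unlist(gl[guild_cols], use.names = FALSE), fillers)
  counts <- withr::with_seed(p$seed, {
    sapply(seq_len(nrow(p$targets)), function(i) {
      probs <- numeric(0)
      for (gc in guild_cols) {
        k <- length(gl[[gc]])
        probs <- c(probs, rep(p$targets[[gc]][i] / k, k))
      }
      rest <- 1 - sum(probs)
      probs <- c(probs, rep(rest / length(fillers), length(fillers)))
      rmultinom(1, p$n_reads, probs)[, 1]
    })
  })
  counts <- matrix(counts, nrow = length(lineages),
                   dimnames = list(NULL, p$targets$sample_id))
  tab <- dplyr::bind_cols(tibble::tibble(lineage = lineages),
                          tibble::as_tibble(counts))
  list(table = tab, truth = p$targets)
}

#' Analytically solved speciation fixture
#'
#' Builds a carbonate-system site sample whose self-consistent ionic
#' strength equals `I_target` exactly (the Na/Cl filler is solved for in
#' closed form), together with the closed-form expected molalities,
#' activity coefficients and activities at fixed pH. Used as an exact
#' oracle for the speciation solver.
#'
#' @param pH Fixed pH.
#' @param T_K Temperature, kelvin.
#' @param dic_uM Dissolved inorganic carbon, umol/L.
#' @param I_target Target ionic strength, mol/kg.
#' @param scenario The [energy_scenario()] the fixture will be speciated
#'   under (its trace-product ions enter the ionic-strength bookkeeping).
#' @return List: `sample` (one-row site tibble), `filler_na_cl_mM`,
#'   `expected` (tibble: species, molality, gamma, activity),
#'   `ionic_strength_molal`.
#' @export
known_speciation_case <- function(pH, T_K = T_REF_K, dic_uM = 0, I_target = 0,
                                  scenario = energy_scenario()) {
  ks <- equilibrium_constants(T_K)
  h <- 10^(-pH)
  g1 <- activity_coefficient(1L, I_target, T_K)
  g2 <- activity_coefficient(2L, I_target, T_K)
  K1p <- ks$K1_carbonic / g1
  K2p <- ks$K2_carbonic * g1 / g2
  a0 <- 1 / (1 + K1p / h + K1p * K2p / h^2)
  a1 <- a0 * K1p / h
  a2 <- a1 * K2p / h
  dic <- dic_uM * 1e-6
  m <- c("H+" = h / g1, "OH-" = ks$Kw / h / g1,
         "CO2(aq)" = dic * a0, "HCO3-" = dic * a1, "CO3-2" = dic * a2)
  z <- c(1, -1, 0, -1, -2)
  # the two monovalent trace-product ions (NO2-, HS-) count toward I too
  S <- sum(m * z^2) + 2 * scenario$trace_product_uM * 1e-6
  # With Na+ = Cl- = filler, I = 0.5 * (2 * filler + S); choosing
  # filler = I_target - S/2 makes I_target the solver's exact fixed point.
  filler <- I_target - S / 2
  if (filler < -1e-6) {
    abort(sprintf("I_target %.3g too small for this chemistry (needs >= %.3g)",
                  I_target, S / 2))
  }
  # I_target = 0 (pure-water fixture): own-ion ionic strength ~1e-7 cannot
  # be cancelled; clamp to zero filler. Gamma-free activities (H+, OH-,
  # CO2) stay exact; molalities of charged species carry O(sqrt(I)) error.
  filler <- max(filler, 0)
  g <- vapply(as.integer(z), function(zz) activity_coefficient(zz, I_target, T_K),
              numeric(1))
  expected <- tibble::tibble(species = names(m), molality = unname(m),
                             gamma = unname(g), activity = unname(m * g))
  sample <- tibble::tibble(
    site_id = sprintf("oracle pH %.2f DIC %g", pH, dic_uM),
    site_type = "spring", temperature_C = T_K - 273.15, pH = pH,
    conductivity_uS_cm = NA_real_, tds_ppm = NA_real_, salinity_ppm = NA_real_,
    orp_mV = NA_real_, doc_uM = 0, dic_uM = dic_uM, d13C_CO2_permil = NA_real_,
    tdn_uM = NA_real_, nox_uM = 0, no2_uM = 0, nh4_uM = 0, don_uM = NA_real_,
    po4_uM = 0, tdp_uM = NA_real_, ch4_uM = 0, d13C_CH4_permil = NA_real_,
    h2_uM = 0, d18O_permil = NA_real_, d2H_permil = NA_real_, so4_uM = NA_real_
  )
  list(sample = sample, filler_na_cl_mM = filler * 1e3, expected = expected,
       ionic_strength_molal = if (filler > 0) I_target else S / 2)
}
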