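# Equilibrium aqueous speciation at measured pH and temperature.
#
# pH is taken as measured and held fixed (a(H+) = 10^-pH); the solver
# partitions the carbonate, ammonium, and phosphate systems among their
# protonation states using equilibrium constants derived from the embedded
# formation-energy table, with Davies activity corrections, and solves the
# ionic strength self-consistently by fixed-point iteration. Neutral
# dissolved gases (CH4, H2, O2, NH3, CO2) carry unit activity coefficients
# (no salting-out; negligible at these ionic strengths), and molality is
# taken equal to molarity (dilute fluids, density ~1 kg/L).

#' Equilibrium constants at temperature
#'
#' Each constant is `exp(-dG0_rxn(T) / (R T))` with `dG0_rxn(T)` from
#' [delta_g_standard()] applied to the corresponding dissociation reaction
#' over the embedded species table, so the speciation module and the
#' reaction energetics share one thermodynamic basis.
#'
#' @param T_K Temperature in kelvin, within (273.15, 373.15).
#' @return List of class `equilibrium_constants`: `temperature_K`, `Kw`,
#'   `K1_carbonic`, `K2_carbonic`, `Ka_ammonium`, `Ka_acetate`,
#'   `Ka2_phosphoric`, `Ka3_phosphoric`.
#' @export
equilibrium_constants <- function(T_K) {
  if (T_K <= 273.15 || T_K >= 373.15) {
    abort(sprintf("T = %.2f K outside liquid-water range (273.15, 373.15)", T_K))
  }
  diss <- list(
    Kw = c("H2O" = -1, "H+" = 1, "OH-" = 1),
    K1_carbonic = c("CO2(aq)" = -1, "H2O" = -1, "H+" = 1, "HCO3-" = 1),
    K2_carbonic = c("HCO3-" = -1, "H+" = 1, "CO3-2" = 1),
    Ka_ammonium = c("NH4+" = -1, "H+" = 1, "NH3(aq)" = 1),
    Ka_acetate = c("acetic_acid(aq)" = -1, "H+" = 1, "acetate-" = 1),
    Ka2_phosphoric = c("H2PO4-" = -1, "H+" = 1, "HPO4-2" = 1),
    Ka3_phosphoric = c("HPO4-2" = -1, "H+" = 1, "PO4-3" = 1)
  )
  ks <- lapply(names(diss), function(nm) {
    r <- reaction(nm, nm, "dissociation", diss[[nm]])
    dG0 <- delta_g_standard(r, T_K)
    exp(-dG0 * 1000 / (R_GAS_J_MOL_K * T_K))
  })
  names(ks) <- names(diss)
  structure(c(list(temperature_K = T_K), ks), class = "equilibrium_constants")
}

#' Davies activity coefficient
#'
#' `log10 gamma = -A(T) z^2 (sqrt(I)/(1 + sqrt(I)) - 0.3 I)`, with the
#' Debye-Huckel slope `A(T) = 0.4883 + 8.074e-4 t(C)` (0.509 at 25 C).
#' Valid to roughly I = 0.5 molal; these fluids sit near I ~ 0.015.
#' Neutral species return 1 by convention.
#'
#' @param charge Integer ionic charge (|z| <= 4).
#' @param ionic_strength Ionic strength, mol/kg (>= 0).
#' @param T_K Temperature in kelvin.
#' @return Activity coefficient gamma (unitless).
#' @export
activity_coefficient <- function(charge, ionic_strength, T_K = T_REF_K) {
  if (any(ionic_strength < 0)) abort("ionic strength must be >= 0")
  if (any(abs(charge) > 4)) abort("|charge| must be <= 4")
  A <- 0.4883 + 8.074e-4 * (T_K - 273.15)
  sI <- sqrt(ionic_strength)
  log10g <- -A * charge^2 * (sI / (1 + sI) - 0.3 * ionic_strength)
  ifelse(charge == 0, 1, 10^log10g)
}

# Air-saturation dissolved O2 (umol/L) for fresh water at 1 atm total
# pressure, linearly interpolated from a standard solubility table
# (Benson & Krause-type values; 258 uM at 25 C).
O2_AIR_SAT_TABLE <- data.frame(
  temperature_C = c(20, 25, 30, 35),
  o2_uM = c(284.1, 258.1, 236.3, 217.2)
)

#' Air-saturation O2 solubility
#'
#' @param T_C Temperature in Celsius (15-40; the table covers 20-35 C and
#'   is linearly extrapolated at most 5 C beyond either end).
#' @return Dissolved O2 at equilibrium with air, umol/L.
#' @export
air_saturation_o2_uM <- function(T_C) {
  if (any(T_C < 15) || any(T_C > 40)) {
    abort("temperature outside the 15-40 C range of the O2 solubility table")
  }
  tab <- O2_AIR_SAT_TABLE
  # approx with rule = 2 then linear extension beyond the table edges
  slope_lo <- (tab$o2_uM[2] - tab$o2_uM[1]) / (tab$temperature_C[2] - tab$temperature_C[1])
  slope_hi <- (tab$o2_uM[4] - tab$o2_uM[3]) / (tab$temperature_C[4] - tab$temperature_C[3])
  out <- approx(tab$temperature_C, tab$o2_uM, xout = pmin(pmax(T_C, 20), 35))$y
  out <- ifelse(T_C < 20, tab$o2_uM[1] + slope_lo * (T_C - 20), out)
  ifelse(T_C > 35, tab$o2_uM[4] + slope_hi * (T_C - 35), out)
}

# Scenario-derived totals (all umol/L).
scenario_acetate_uM <- function(doc_uM, scenario) {
  if (is.na(doc_uM)) return(NA_real_)
  if (scenario$acetate_basis == "carbon") {
    scenario$acetate_fraction_doc * doc_uM / 2  # two carbons per acetate
  } else {
    scenario$acetate_fraction_doc * doc_uM
  }
}

# One pass of the fixed-pH partitioning at a given ionic strength.
# Returns list(species = tibble, I = implied ionic strength).
partition_at_I <- function(tot, aH, ks, I, T_K, trace_uM) {
  g1 <- activity_coefficient(1L, I, T_K)
  g2 <- activity_coefficient(2L, I, T_K)
  g3 <- activity_coefficient(3L, I, T_K)

  mH <- aH / g1
  mOH <- (ks$Kw / aH) / g1

  # carbonate: m ratios include activity corrections (gamma(CO2) = 1)
  r1 <- ks$K1_carbonic / (aH * g1)
  r2 <- ks$K2_carbonic * g1 / (aH * g2)
  den <- 1 + r1 + r1 * r2
  mCO2 <- tot$dic / den
  mHCO3 <- mCO2 * r1
  mCO3 <- mHCO3 * r2

  # ammonium
  rN <- ks$Ka_ammonium * g1 / aH
  mNH4 <- tot$nh4 / (1 + rN)
  mNH3 <- tot$nh4 - mNH4

  # phosphate (H3PO4 negligible above pH ~6)
  rB <- ks$Ka2_phosphoric * g1 / (aH * g2)
  rC <- ks$Ka3_phosphoric * g2 / (aH * g3)
  denP <- 1 + rB + rB * rC
  mH2PO4 <- tot$po4 / denP
  mHPO4 <- mH2PO4 * rB
  mPO4 <- mHPO4 * rC

  trace <- trace_uM * 1e-6
  mNO2 <- if (tot$no2 > 0) tot$no2 else trace
  no2_assumed <- tot$no2 <= 0
  mHS <- if (tot$hs > 0) tot$hs else trace
  hs_assumed <- tot$hs <= 0

  sp <- tibble::tibble(
    species = c("H+", "OH-", "CO2(aq)", "HCO3-", "CO3-2", "NH4+", "NH3(aq)",
                "CH4(aq)", "H2(aq)", "O2(aq)", "acetate-", "SO4-2", "NO3-",
                "NO2-", "H2PO4-", "HPO4-2", "PO4-3", "HS-", "Na+", "Cl-"),
    charge = c(1L, -1L, 0L, -1L, -2L, 1L, 0L,
               0L, 0L, 0L, -1L, -2L, -1L,
               -1L, -1L, -2L, -3L, -1L, 1L, -1L),
    molality = c(mH, mOH, mCO2, mHCO3, mCO3, mNH4, mNH3,
                 tot$ch4, tot$h2, tot$o2, tot$acetate, tot$so4, tot$no3,
                 mNO2, mH2PO4, mHPO4, mPO4, mHS, tot$na, tot$cl),
    assumed = c(rep(FALSE, 13), no2_assumed, FALSE, FALSE, FALSE,
                hs_assumed, FALSE, FALSE)
  )
  sp$gamma <- vapply(sp$charge, function(z) activity_coefficient(z, I, T_K), numeric(1))
  sp$activity <- sp$gamma * sp$molality
  I_implied <- 0.5 * sum(sp$molality * sp$charge^2)
  list(species = sp, I = I_implied)
}

# Collect the totals (mol/kg) entering speciation for one site + scenario.
speciation_totals <- function(s, filler_na_cl_mM, scenario) {
  num <- function(f) {
    x <- s[[f]]
    if (is.null(x) || is.na(x)) 0 else as.numeric(x)
  }
  no2 <- num("no2_uM")
  no3 <- max(num("nox_uM") - no2, 0)
  so4 <- if (is.null(s[["so4_uM"]]) || is.na(s[["so4_uM"]])) {
    if (is.na(scenario$assumed_so4_uM)) 0 else scenario$assumed_so4_uM
  } else {
    as.numeric(s[["so4_uM"]])
  }
  acet <- scenario_acetate_uM(num("doc_uM"), scenario)
  list(
    dic = num("dic_uM") * 1e-6,
    nh4 = num("nh4_uM") * 1e-6,
    po4 = num("po4_uM") * 1e-6,
    ch4 = num("ch4_uM") * 1e-6,
    h2 = num("h2_uM") * 1e-6,
    o2 = scenario$o2_fraction_air_sat *
      air_saturation_o2_uM(as.numeric(s[["temperature_C"]])) * 1e-6,
    acetate = (if (is.na(acet)) 0 else acet) * 1e-6,
    so4 = so4 * 1e-6,
    no3 = no3 * 1e-6,
    no2 = no2 * 1e-6,
    hs = 0,
    na = filler_na_cl_mM * 1e-3,
    cl = filler_na_cl_mM * 1e-3
  )
}

check_speciation_preconditions <- function(s) {
  for (f in c("pH", "temperature_C", "dic_uM")) {
    if (is.null(s[[f]]) || is.na(s[[f]])) {
      abort(sprintf("site %s: required field '%s' is missing",
                    s[["site_id"]] %||% "?", f))
    }
  }
  v <- validate_sample(s)
  if (length(v) > 0) {
    abort(sprintf("site %s fails validation: %s",
                  s[["site_id"]] %||% "?", paste(v, collapse = "; ")))
  }
}

#' Speciate a site's fluid at its measured pH and temperature
#'
#' Partitions the measured totals among protonation states at fixed
#' `a(H+) = 10^-pH`, with Davies activity corrections, solving ionic
#' strength by fixed-point iteration to a relative tolerance of 1e-10.
#' Dissolved O2 and acetate are scenario assumptions (fraction of
#' air-saturation solubility and fraction of DOC respectively); Na+ and Cl-
#' are nominal filler ions standing in for the measured salinity. Product
#' species with zero measured totals (NO2- at the springs, unmeasured HS-)
#' receive the scenario's nominal trace concentration and are flagged
#' `assumed` in the output.
#'
#' @param s One site row (tibble row or named list).
#' @param filler_na_cl_mM Nominal Na+ = Cl- concentration, mmol/L
#'   (default 12.5, midpoint of the 10-15 mM used for these fluids).
#' @param scenario An [energy_scenario()].
#' @return List of class `speciated_fluid`: `site_id`, `pH`,
#'   `temperature_K`, `ionic_strength_molal`, `iterations`, `residual`,
#'   and a `species` tibble (species, charge, molality, gamma, activity,
#'   assumed).
#' @export
speciate <- function(s, filler_na_cl_mM = 12.5, scenario = energy_scenario()) {
  s <- as.list(s)
  check_speciation_preconditions(s)
  T_K <- as.numeric(s$temperature_C) + 273.15
  aH <- 10^(-as.numeric(s$pH))
  ks <- equilibrium_constants(T_K)
  tot <- speciation_totals(s, filler_na_cl_mM, scenario)

  I <- 0
  res <- NULL
  converged <- FALSE
  for (iter in seq_len(100)) {
    res <- partition_at_I(tot, aH, ks, I, T_K, scenario$trace_product_uM)
    dI <- abs(res$I - I) / max(res$I, 1e-12)
    I <- res$I
    if (dI <= 1e-10) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(sprintf("ionic-strength iteration did not converge for site %s (last relative step %.3g)",
                  s$site_id %||% "?", dI))
  }
  # largest relative residual over the equilibria actually used
  sp <- res$species
  act <- setNames(sp$activity, sp$species)
  rel <- function(lhs, K) abs(lhs - K) / K
  residual <- max(
    rel(aH * act[["OH-"]], ks$Kw),
    if (tot$dic > 0) rel(aH * act[["HCO3-"]] / act[["CO2(aq)"]], ks$K1_carbonic) else 0,
    if (tot$dic > 0) rel(aH * act[["CO3-2"]] / act[["HCO3-"]], ks$K2_carbonic) else 0,
    if (tot$nh4 > 0) rel(aH * act[["NH3(aq)"]] / act[["NH4+"]], ks$Ka_ammonium) else 0,
    if (tot$po4 > 0) rel(aH * act[["HPO4-2"]] / act[["H2PO4-"]], ks$Ka2_phosphoric) else 0,
    if (tot$po4 > 0) rel(aH * act[["PO4-3"]] / act[["HPO4-2"]], ks$Ka3_phosphoric) else 0
  )
  structure(list(
    site_id = s$site_id %||% "?",
    pH = as.numeric(s$pH),
    temperature_K = T_K,
    ionic_strength_molal = I,
    iterations = iter,
    residual = residual,
    species = sp[, c("species", "charge", "molality", "gamma", "activity", "assumed")]
  ), class = "speciated_fluid")
}

#' @export
print.speciated_fluid <- function(x, ...) {
  cat(sprintf("<speciated_fluid> %s  pH %.2f  T %.2f K  I %.4g molal (%d iterations)\n",
              x$site_id, x$pH, x$temperature_K, x$ionic_strength_molal, x$iterations))
  print(x$species, n = nrow(x$species))
  invisible(x)
}

#' Independent closed-form speciation oracle
#'
#' Same contract as [speciate()], but computed by direct evaluation of the
#' polyprotic ionization fractions (alpha expressions) at fixed pH, with the
#' self-consistent ionic strength located by a coarse grid search bracketing
#' the root of `I_implied(I) - I` followed by [stats::uniroot()] — no
#' fixed-point iteration. Used to cross-check the solver in tests.
#'
#' @inheritParams speciate
#' @return A `speciated_fluid` (same structure as [speciate()]).
#' @export
speciation_oracle <- function(s, filler_na_cl_mM = 12.5, scenario = energy_scenario()) {
  s <- as.list(s)
  check_speciation_preconditions(s)
  T_K <- as.numeric(s$temperature_C) + 273.15
  h <- 10^(-as.numeric(s$pH))
  ks <- equilibrium_constants(T_K)
  tot <- speciation_totals(s, filler_na_cl_mM, scenario)
  trace <- scenario$trace_product_uM * 1e-6

  implied_I <- function(I) {
    g1 <- activity_coefficient(1L, I, T_K)
    g2 <- activity_coefficient(2L, I, T_K)
    g3 <- activity_coefficient(3L, I, T_K)
    # carbonate alphas via apparent (molality-basis) constants
    K1p <- ks$K1_carbonic / g1
    K2p <- ks$K2_carbonic * g1 / g2
    a0 <- 1 / (1 + K1p / h + K1p * K2p / h^2)
    a1 <- a0 * K1p / h
    a2 <- a1 * K2p / h
    # ammonium
    KNp <- ks$Ka_ammonium * g1
    fNH4 <- 1 / (1 + KNp / h)
    # phosphate
    KBp <- ks$Ka2_phosphoric * g1 / g2
    KCp <- ks$Ka3_phosphoric * g2 / g3
    p0 <- 1 / (1 + KBp / h + KBp * KCp / h^2)
    p1 <- p0 * KBp / h
    p2 <- p1 * KCp / h
    m <- c(
      "H+" = h / g1, "OH-" = ks$Kw / h / g1,
      "CO2(aq)" = tot$dic * a0, "HCO3-" = tot$dic * a1, "CO3-2" = tot$dic * a2,
      "NH4+" = tot$nh4 * fNH4, "NH3(aq)" = tot$nh4 * (1 - fNH4),
      "CH4(aq)" = tot$ch4, "H2(aq)" = tot$h2, "O2(aq)" = tot$o2,
      "acetate-" = tot$acetate, "SO4-2" = tot$so4, "NO3-" = tot$no3,
      "NO2-" = if (tot$no2 > 0) tot$no2 else trace,
      "H2PO4-" = tot$po4 * p0, "HPO4-2" = tot$po4 * p1, "PO4-3" = tot$po4 * p2,
      "HS-" = if (tot$hs > 0) tot$hs else trace,
      "Na+" = tot$na, "Cl-" = tot$cl
    )
    z <- c(1, -1, 0, -1, -2, 1, 0, 0, 0, 0, -1, -2, -1, -1, -1, -2, -3, -1, 1, -1)
    list(I = 0.5 * sum(m * z^2), m = m, z = z,
         g = vapply(z, function(zz) activity_coefficient(as.integer(zz), I, T_K), numeric(1)))
  }

  f <- function(I) implied_I(I)$I - I
  # coarse grid to bracket the fixed point, then uniroot
  grid <- c(0, 10^seq(-6, 0, length.out = 40))
  fv <- vapply(grid, f, numeric(1))
  sgn <- sign(fv)
  k <- which(sgn[-1] * sgn[-length(sgn)] <= 0)[1]
  if (is.na(k)) abort("oracle could not bracket the ionic-strength root")
  if (fv[k] == 0) {
    I_star <- grid[k]
  } else {
    I_star <- uniroot(f, c(grid[k], grid[k + 1]), tol = 1e-14)$root
  }
  sol <- implied_I(I_star)
  sp <- tibble::tibble(
    species = names(sol$m),
    charge = as.integer(sol$z),
    molality = unname(sol$m),
    gamma = unname(sol$g),
    assumed = names(sol$m) %in% c(if (tot$no2 <= 0) "NO2-", if (tot$hs <= 0) "HS-")
  )
  sp$activity <- sp$gamma * sp$molality
  structure(list(
    site_id = s$site_id %||% "?",
    pH = as.numeric(s$pH),
    temperature_K = T_K,
    ionic_strength_molal = sol$I,
    iterations = NA_integer_,
    residual = NA_real_,
    species = sp[, c("species", "charge", "molality", "gamma", "activity", "assumed")]
  ), class = "speciated_fluid")
}

#' Serialize a speciated fluid to a long tibble
#'
#' @param fluid A `speciated_fluid`.
#' @return Tibble: `site_id`, `species`, `molality`, `gamma`, `activity`,
#'   `assumed`.
#' @export
speciation_long <- function(fluid) {
  dplyr::mutate(fluid$species, site_id = fluid$site_id, .before = 1)
}
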