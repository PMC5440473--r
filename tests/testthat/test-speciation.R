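# Speciation: equilibrium constants, Davies activity model, the fixed-pH
# solver, mass balance, and agreement with the closed-form oracle.

test_that("derived equilibrium constants reproduce the textbook pK values at 25 C", {
  ks <- equilibrium_constants(298.15)
  expect_equal(ks$temperature_K, 298.15)
  # hand oracles: pK = dG0(rxn) * 1000 / (R T ln 10) from the embedded table
  RTln10 <- 8.314 * 298.15 * log(10)
  pKw_oracle <- (0 + (-157.30) - (-237.18)) * 1000 / RTln10
  pK1_oracle <- ((-586.94) + 0 - (-385.97) - (-237.18)) * 1000 / RTln10
  pK2_oracle <- ((-527.98) + 0 - (-586.94)) * 1000 / RTln10
  expect_equal(-log10(ks$Kw), pKw_oracle, tolerance = 1e-9)
  expect_equal(-log10(ks$K1_carbonic), pK1_oracle, tolerance = 1e-9)
  expect_equal(-log10(ks$K2_carbonic), pK2_oracle, tolerance = 1e-9)
  # and the oracles themselves sit at the known constants
  expect_equal(pKw_oracle, 14.0, tolerance = 0.05)
  expect_equal(pK1_oracle, 6.3, tolerance = 0.1)
  expect_equal(pK2_oracle, 10.3, tolerance = 0.1)
  expect_equal(-log10(ks$Ka_ammonium), 9.25, tolerance = 0.05)
  expect_equal(-log10(ks$Ka_acetate), 4.76, tolerance = 0.05)
  expect_error(equilibrium_constants(250), "range")
  expect_error(equilibrium_constants(400), "range")
})

test_that("Davies activity coefficients match hand evaluation and limits", {
  expect_equal(activity_coefficient(1L, 0, 298.15), 1)
  expect_equal(activity_coefficient(-3L, 0, 298.15), 1)
  expect_equal(activity_coefficient(0L, 0.1, 298.15), 1)  # neutral convention
  # hand: log10 g = -0.509 * (sqrt(.01)/(1+sqrt(.01)) - 0.3*0.01) = -0.04475
  expect_equal(activity_coefficient(1L, 0.01, 298.15), 0.902, tolerance = 5e-4)
  expect_equal(activity_coefficient(-1L, 0.01, 298.15),
               activity_coefficient(1L, 0.01, 298.15))
  # gamma decreasing in z^2 at fixed moderate I
  for (I in c(1e-4, 1e-3, 0.01, 0.1, 0.3)) {
    g <- sapply(1:4, function(z) activity_coefficient(z, I, 298.15))
    expect_true(all(diff(g) < 0))
    expect_true(all(g > 0 & g <= 1.5))
  }
  # gamma -> 1 as I -> 0 for all charges
  for (z in 1:4) {
    expect_equal(activity_coefficient(z, 1e-12, 298.15), 1, tolerance = 1e-4)
    expect_equal(activity_coefficient(z, 1e-15, 298.15), 1, tolerance = 1e-6)
  }
  expect_error(activity_coefficient(1L, -0.1, 298.15), ">= 0")
  expect_error(activity_coefficient(5L, 0.1, 298.15), "charge")
})

test_that("pure water at pH 7 and 25 C is (near-)neutral", {
  pw <- minimal_site(site_type = "spring", temperature_C = 25, pH = 7,
                     dic_uM = 0, doc_uM = 0, ch4_uM = 0, h2_uM = 0,
                     nox_uM = 0, nh4_uM = 0, po4_uM = 0)
  sp <- speciate(pw, filler_na_cl_mM = 0)
  a <- setNames(sp$species$activity, sp$species$species)
  expect_identical(a[["H+"]], 1e-7)  # fixed by construction
  # the embedded formation energies give pKw 13.99, so a(OH-) sits within
  # 2e-9 of 1e-7 rather than exactly on it
  expect_equal(a[["OH-"]], 1e-7, tolerance = 2e-2)
  expect_lt(abs(a[["OH-"]] - 1e-7), 2e-9)
})

test_that("carbonate partitioning follows the closed-form ionization fractions", {
  # hyperalkaline spring conditions: carbonate ion dominates, CO2 vanishes
  s8 <- minimal_site(pH = 11.54, temperature_C = 26.1, dic_uM = 227.0)
  sp <- speciate(s8)
  m <- setNames(sp$species$molality, sp$species$species)
  dic <- 227.0e-6
  expect_equal(m[["CO2(aq)"]] + m[["HCO3-"]] + m[["CO3-2"]], dic,
               tolerance = 1e-6)
  expect_gt(m[["CO3-2"]], m[["HCO3-"]])
  expect_lt(m[["CO2(aq)"]] / dic, 1e-4)
  # circumneutral background: bicarbonate dominates
  up <- minimal_site(pH = 8.42, temperature_C = 27.9, dic_uM = 597.3)
  spu <- speciate(up)
  mu <- setNames(spu$species$molality, spu$species$species)
  expect_gt(mu[["HCO3-"]] / 597.3e-6, 0.9)
  # closed-form oracle at the solved ionic strength agrees
  ks <- equilibrium_constants(26.1 + 273.15)
  g1 <- activity_coefficient(1L, sp$ionic_strength_molal, 26.1 + 273.15)
  g2 <- activity_coefficient(2L, sp$ionic_strength_molal, 26.1 + 273.15)
  h <- 10^(-11.54)
  K1p <- ks$K1_carbonic / g1
  K2p <- ks$K2_carbonic * g1 / g2
  a0 <- 1 / (1 + K1p / h + K1p * K2p / h^2)
  expect_equal(m[["CO2(aq)"]], dic * a0, tolerance = 1e-9)
})

test_that("mass balance and equilibrium residuals hold for the field fixture", {
  f <- load_seo_fixture()
  for (i in seq_len(nrow(f))) {
    sp <- speciate(f[i, ])
    m <- setNames(sp$species$molality, sp$species$species)
    a <- setNames(sp$species$activity, sp$species$species)
    dic <- f$dic_uM[i] * 1e-6
    expect_equal(m[["CO2(aq)"]] + m[["HCO3-"]] + m[["CO3-2"]], dic,
                 tolerance = 1e-6 * dic, label = paste("DIC balance", f$site_id[i]))
    nh4 <- f$nh4_uM[i] * 1e-6
    expect_equal(m[["NH4+"]] + m[["NH3(aq)"]], nh4, tolerance = 1e-6 * max(nh4, 1e-12))
    po4 <- f$po4_uM[i] * 1e-6
    expect_equal(m[["H2PO4-"]] + m[["HPO4-2"]] + m[["PO4-3"]], po4,
                 tolerance = 1e-6 * max(po4, 1e-12))
    expect_equal(a[["H+"]], 10^(-f$pH[i]), tolerance = 1e-12)
    expect_lt(sp$residual, 1e-8)
    expect_true(all(m >= 0))
    expect_true(all(sp$species$gamma > 0 & sp$species$gamma <= 1.5))
  }
})

test_that("raising pH at fixed DIC never raises dissolved CO2", {
  phs <- seq(6, 12, by = 0.5)
  mco2 <- sapply(phs, function(p) {
    sp <- speciate(minimal_site(pH = p, dic_uM = 300))
    sp$species$molality[sp$species$species == "CO2(aq)"]
  })
  expect_true(all(diff(mco2) <= 0))
})

test_that("speciate is a pure function of its arguments", {
  s <- minimal_site(pH = 11.2, dic_uM = 180)
  a <- speciate(s)
  b <- speciate(s)
  expect_identical(a$species, b$species)
  expect_identical(a$ionic_strength_molal, b$ionic_strength_molal)
})

test_that("solver and closed-form oracle agree to 1e-6 on random valid fluids", {
  set.seed(402)
  n_ok <- 0
  worst <- 0
  for (k in 1:100) {
    s <- minimal_site(
      pH = runif(1, 6.5, 12), temperature_C = runif(1, 20, 34),
      dic_uM = runif(1, 50, 800), doc_uM = runif(1, 5, 120),
      ch4_uM = runif(1, 0.1, 1000), h2_uM = runif(1, 0.1, 60),
      nox_uM = runif(1, 0, 60), no2_uM = 0, nh4_uM = runif(1, 0, 5),
      po4_uM = runif(1, 0, 3))
    a <- speciate(s)
    b <- speciation_oracle(s)
    m <- merge(a$species, b$species, by = "species")
    keep <- m$activity.y > 0
    rel <- max(abs(m$activity.x[keep] - m$activity.y[keep]) / m$activity.y[keep])
    worst <- max(worst, rel)
    n_ok <- n_ok + (rel <= 1e-6)
  }
  expect_equal(n_ok, 100)
  expect_lt(worst, 1e-6)
})

test_that("speciation preconditions are enforced", {
  s <- minimal_site()
  s$dic_uM <- NA_real_
  expect_error(speciate(s), "dic_uM")
  bad <- minimal_site(pH = 15)
  expect_error(speciate(bad), "validation")
})

test_that("O2 air-saturation solubility interpolates the embedded table", {
  expect_equal(air_saturation_o2_uM(25), 258.1)
  expect_equal(air_saturation_o2_uM(20), 284.1)
  expect_equal(air_saturation_o2_uM(22.5), (284.1 + 258.1) / 2)
  expect_true(all(diff(air_saturation_o2_uM(seq(16, 39, 1))) < 0))
  expect_error(air_saturation_o2_uM(50), "range")
})

test_that("scenario assumptions feed O2 and acetate into the speciated fluid", {
  s <- minimal_site(temperature_C = 25, doc_uM = 73.2)
  sc <- energy_scenario(o2_fraction_air_sat = 0.01, acetate_fraction_doc = 0.10)
  sp <- speciate(s, scenario = sc)
  a <- setNames(sp$species$molality, sp$species$species)
  expect_equal(a[["O2(aq)"]], 0.01 * 258.1 * 1e-6)
  # carbon basis: 10% of 73.2 uM DOC carbon = 3.66 uM acetate
  expect_equal(a[["acetate-"]], 3.66e-6)
  sc_m <- energy_scenario(acetate_fraction_doc = 0.10, acetate_basis = "molar")
  sp_m <- speciate(s, scenario = sc_m)
  expect_equal(sp_m$species$molality[sp_m$species$species == "acetate-"], 7.32e-6)
})
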