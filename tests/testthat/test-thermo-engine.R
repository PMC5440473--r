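# Reaction catalog, standard-state energetics, and the dG = dG0 + RT lnQ
# engine, checked against hand-summed formation energies and hand
# arithmetic on prescribed activities.

R_GAS <- 8.314

test_that("default catalog has the five methane-cycling reactions, all balanced", {
  cat5 <- default_reaction_catalog()
  expect_length(cat5, 5)
  expect_setequal(names(cat5), c("MG", "AM", "AOM_SO4", "AOM_NO3", "AeMO"))
  for (r in cat5) expect_length(check_balance(r), 0)
  # MG availability is measured as bulk DIC and dissolved H2
  expect_equal(cat5$MG$limiting,
               c("CO2(aq)" = "dic_uM", "H2(aq)" = "h2_uM"))
  expect_equal(unname(cat5$MG$stoichiometry[c("CO2(aq)", "H2(aq)", "CH4(aq)", "H2O")]),
               c(-1, -4, 1, 2))
})

test_that("check_balance flags deliberate element and charge imbalance", {
  malformed <- reaction("bad", "CH4 + O2 -> HCO3-", "aerobic_methanotrophy",
                        c("CH4(aq)" = -1, "O2(aq)" = -1, "HCO3-" = 1))
  v <- check_balance(malformed)
  expect_true(any(grepl("element H", v)))
  expect_true(any(grepl("element O", v)))
  expect_true(any(grepl("charge", v)))
  expect_error(check_balance(reaction("x", "x", "methanogenesis", c(Unobtainium = -1))),
               "unknown species")
})

test_that("dG0 at 25 C equals the hand-summed formation energies", {
  cat5 <- default_reaction_catalog()
  # oracle: explicit sums over the embedded constants
  # MG: CO2(aq) + 4 H2(aq) -> CH4(aq) + 2 H2O
  mg_oracle <- (-34.45) + 2 * (-237.18) - (-385.97) - 4 * 17.72
  expect_equal(mg_oracle, -193.72, tolerance = 1e-10)
  expect_equal(delta_g_standard(cat5$MG, 298.15), mg_oracle, tolerance = 1e-9)
  # AM: acetate- + H2O -> CH4(aq) + HCO3-
  am_oracle <- (-34.45) + (-586.94) - (-369.32) - (-237.18)
  expect_equal(am_oracle, -14.89, tolerance = 1e-10)
  expect_equal(delta_g_standard(cat5$AM, 298.15), am_oracle, tolerance = 1e-9)
  # AOM_NO3: CH4 + 4 NO3- -> HCO3- + 4 NO2- + H+ + H2O
  no3_oracle <- (-586.94) + 4 * (-32.22) + 0 + (-237.18) -
    (-34.45) - 4 * (-110.91)
  expect_equal(delta_g_standard(cat5$AOM_NO3, 298.15), no3_oracle, tolerance = 1e-9)
  # at T = T0 the van 't Hoff correction vanishes for any reaction
  for (r in cat5) {
    st <- r$stoichiometry
    tab <- thermo_species_table()
    direct <- sum(st * tab$dGf_25C_kJ_mol[match(names(st), tab$species)])
    expect_equal(delta_g_standard(r, 298.15), direct, tolerance = 1e-12)
  }
  expect_error(delta_g_standard(cat5$MG, 350), "window")
  expect_error(delta_g_standard(cat5$MG, 280), "window")
})

test_that("lnQ is the signed sum of log activities with unit-activity water", {
  cat5 <- default_reaction_catalog()
  fl <- fake_fluid(c("CO2(aq)" = 1, "H2(aq)" = 1, "CH4(aq)" = 1), pH = 0)
  expect_equal(activity_quotient(cat5$MG, fl), 0)
  # hand arithmetic on prescribed spring-like activities
  fl2 <- fake_fluid(c("CO2(aq)" = 7.5e-11, "H2(aq)" = 1.1e-5, "CH4(aq)" = 8.7e-4))
  lnQ <- activity_quotient(cat5$MG, fl2)
  expect_equal(lnQ, log(8.7e-4) - log(7.5e-11) - 4 * log(1.1e-5), tolerance = 1e-12)
  expect_equal(lnQ, 61.9, tolerance = 0.05)
  # reversal negates lnQ
  expect_equal(activity_quotient(reverse_reaction(cat5$MG), fl2), -lnQ)
  # zero activity is an error naming the species
  fl3 <- fake_fluid(c("CO2(aq)" = 0, "H2(aq)" = 1e-5, "CH4(aq)" = 1e-4))
  expect_error(activity_quotient(cat5$MG, fl3), "CO2\\(aq\\)")
})

test_that("dG = dG0 + RT lnQ holds exactly and matches the full hand chain", {
  cat5 <- default_reaction_catalog()
  # Q = 1 limit
  fl <- fake_fluid(c("CO2(aq)" = 1, "H2(aq)" = 1, "CH4(aq)" = 1), T_K = 298.15)
  en <- delta_g(cat5$MG, fl)
  expect_equal(en$dG_kJ_mol, en$dG0_kJ_mol)
  # re-addition identity on arbitrary activities
  fl2 <- fake_fluid(c("CO2(aq)" = 7.5e-11, "H2(aq)" = 1.1e-5, "CH4(aq)" = 8.7e-4),
                    T_K = 299.25)
  en2 <- delta_g(cat5$MG, fl2)
  expect_identical(en2$dG_kJ_mol,
                   en2$dG0_kJ_mol + R_GAS * 299.25 * en2$lnQ / 1000)
  # full hand chain: van 't Hoff dG0 + RT lnQ at 299.25 K
  tau <- 299.25 / 298.15
  mg_dH <- (-87.91) + 2 * (-285.83) - (-413.80) - 4 * (-4.18)
  dG0_oracle <- (-193.72) * tau + mg_dH * (1 - tau)
  lnQ_oracle <- log(8.7e-4) - log(7.5e-11) - 4 * log(1.1e-5)
  expect_equal(en2$dG_kJ_mol, dG0_oracle + R_GAS * 299.25 * lnQ_oracle / 1000,
               tolerance = 1e-9)
  expect_equal(en2$dG_kJ_mol, -40, tolerance = 1)
  # equilibrium: activities tuned so lnQ = -dG0 * 1000 / (R T) give dG = 0
  dG0 <- delta_g_standard(cat5$MG, 298.15)
  target_lnQ <- -dG0 * 1000 / (R_GAS * 298.15)
  a_ch4 <- exp(target_lnQ) * 1 * 1^4  # set CH4 alone to hit the target
  fl3 <- fake_fluid(c("CO2(aq)" = 1, "H2(aq)" = 1, "CH4(aq)" = a_ch4))
  expect_equal(delta_g(cat5$MG, fl3)$dG_kJ_mol, 0, tolerance = 1e-9)
})

test_that("forward and reversed reactions have antisymmetric dG", {
  cat5 <- default_reaction_catalog()
  fl <- fake_fluid(c("CO2(aq)" = 2e-11, "H2(aq)" = 4e-5, "CH4(aq)" = 1.5e-4,
                     "HCO3-" = 4e-6, "acetate-" = 3e-7, "NO3-" = 7e-7,
                     "NO2-" = 4e-8, "O2(aq)" = 2.5e-6, "SO4-2" = 1e-5,
                     "HS-" = 5e-8), pH = 11.5, T_K = 300)
  for (r in cat5) {
    fwd <- delta_g(r, fl)$dG_kJ_mol
    rev <- delta_g(reverse_reaction(r), fl)$dG_kJ_mol
    expect_equal(fwd + rev, 0, tolerance = 1e-10,
                 label = paste("antisymmetry for", r$reaction_id))
  }
})

test_that("dG falls when a reactant activity rises and rises with a product", {
  cat5 <- default_reaction_catalog()
  base <- c("CO2(aq)" = 2e-11, "H2(aq)" = 4e-5, "CH4(aq)" = 1.5e-4,
            "HCO3-" = 4e-6, "acetate-" = 3e-7, "NO3-" = 7e-7,
            "NO2-" = 4e-8, "O2(aq)" = 2.5e-6, "SO4-2" = 1e-5, "HS-" = 5e-8)
  for (r in cat5) {
    st <- r$stoichiometry
    for (sp in setdiff(names(st), c("H2O", "H+"))) {
      bumped <- base
      bumped[sp] <- bumped[sp] * 2
      d0 <- delta_g(r, fake_fluid(base, pH = 11, T_K = 300))$dG_kJ_mol
      d1 <- delta_g(r, fake_fluid(bumped, pH = 11, T_K = 300))$dG_kJ_mol
      if (st[[sp]] < 0) {
        expect_lt(d1, d0)
      } else {
        expect_gt(d1, d0)
      }
    }
  }
})
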