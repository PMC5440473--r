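# Limiting-reactant extents, J/L yields, the scenario grid, and rankings.

test_that("limiting reactant is the scarcest per stoichiometric unit", {
  mg <- default_reaction_catalog()$MG
  # Q. Danta totals: DIC 126.3, H2 38.3 -> H2 limits at 38.3/4
  lim <- limiting_reactant(mg, c("CO2(aq)" = 126.3, "H2(aq)" = 38.3))
  expect_equal(lim$species, "H2(aq)")
  expect_equal(lim$extent_umol_L, 9.575)
  # zero reservoir -> zero extent
  lim0 <- limiting_reactant(mg, c("CO2(aq)" = 0, "H2(aq)" = 38.3))
  expect_equal(lim0$extent_umol_L, 0)
  # single-candidate identity (acetoclastic: 1% of 5.6 uM DOC carbon)
  am <- default_reaction_catalog()$AM
  lim_am <- limiting_reactant(am, c("acetate-" = 0.01 * 5.6 / 2))
  expect_equal(lim_am$species, "acetate-")
  expect_equal(lim_am$extent_umol_L, 0.028)
  expect_error(limiting_reactant(mg, c("CO2(aq)" = 1)), "H2\\(aq\\)")
  expect_error(limiting_reactant(mg, c("CO2(aq)" = 1, "H2(aq)" = NA)), "H2\\(aq\\)")
})

test_that("energy per liter is max(0, -dG) x extent / 1000", {
  s <- minimal_site(pH = 11.5, temperature_C = 26, dic_uM = 227, doc_uM = 73.2,
                    ch4_uM = 870.7, h2_uM = 10.9)
  sc <- energy_scenario()
  fl <- speciate(s, scenario = sc)
  mg <- default_reaction_catalog()$MG
  res <- energy_per_liter(mg, fl, s, sc)
  expect_equal(res$extent_umol_L, 10.9 / 4)
  expect_equal(res$energy_J_L,
               max(0, -res$dG_kJ_mol) * res$extent_umol_L / 1000)
  # spec arithmetic check: a -40 kJ/mol reaction at 2.725 umol/L is 0.109 J/L
  expect_equal(40 * 2.725 / 1000, 0.109)
  # endergonic clamp: reversed MG is endergonic here -> zero energy
  rev <- reverse_reaction(mg)
  rev$limiting <- c("CH4(aq)" = "ch4_uM")
  res_rev <- energy_per_liter(rev, fl, s, sc)
  expect_gt(res_rev$dG_kJ_mol, 0)
  expect_equal(res_rev$energy_J_L, 0)
})

test_that("missing sulfate surfaces as an explicit configuration error", {
  s <- minimal_site()
  sc <- energy_scenario()  # assumed_so4_uM = NA
  fl <- speciate(s, scenario = sc)
  aom <- default_reaction_catalog()$AOM_SO4
  expect_error(energy_per_liter(aom, fl, s, sc), "SO4")
  # supplying an assumed sulfate makes the cell computable
  sc2 <- energy_scenario(assumed_so4_uM = 100)
  fl2 <- speciate(s, scenario = sc2)
  res <- energy_per_liter(aom, fl2, s, sc2)
  expect_true(res$energy_J_L >= 0)
  expect_equal(res$limiting_species, "SO4-2")  # 100/1 < 500/1 CH4
})

test_that("energy scales linearly in the limiting total at fixed activities", {
  s <- minimal_site(h2_uM = 20)
  sc <- energy_scenario()
  fl <- speciate(s, scenario = sc)
  mg <- default_reaction_catalog()$MG
  e1 <- energy_per_liter(mg, fl, s, sc)
  s2 <- s
  s2$h2_uM <- 40  # still limiting (40/4 << dic)
  e2 <- energy_per_liter(mg, fl, s2, sc)
  expect_equal(e2$extent_umol_L, 2 * e1$extent_umol_L)
  expect_equal(e2$energy_J_L, 2 * e1$energy_J_L)
})

test_that("scenario grid covers sites x seven cells and records skips", {
  springs <- load_seo_fixture()
  springs <- springs[springs$site_type == "spring", ]
  g <- scenario_grid(springs)
  expect_equal(nrow(g), 3 * 7)
  expect_setequal(unique(g$cell),
                  c("AM(1)", "AM(10)", "MG", "SO4", "NO3", "O2(1)", "O2(0.1)"))
  # sulfate cells are recorded as skipped, not dropped
  so4 <- g[g$cell == "SO4", ]
  expect_true(all(so4$status != "ok"))
  expect_true(all(is.na(so4$energy_J_L)))
  ok <- g[g$status == "ok", ]
  expect_equal(nrow(ok), 3 * 6)
  # every computed row satisfies the result invariant
  expect_equal(ok$energy_J_L,
               pmax(0, -ok$dG_kJ_mol) * ok$extent_umol_L / 1000)
  expect_true(all(ok$energy_J_L[ok$dG_kJ_mol >= 0] == 0))
  # empty site list -> empty result
  expect_equal(nrow(scenario_grid(springs[0, ])), 0)
  # determinism
  expect_equal(scenario_grid(springs), g)
})

test_that("more substrate never yields less energy across scenario brackets", {
  sites <- load_seo_fixture()
  sites <- sites[sites$site_type == "spring", ]
  syn <- simulate_fluid_table(fluid_sim_params(n_spring = 12, n_background = 0,
                                               seed = 11))$samples
  for (tab in list(sites, syn)) {
    g <- scenario_grid(tab)
    for (id in tab$site_id) {
      gi <- g[g$site_id == id, ]
      am <- setNames(gi$energy_J_L[gi$reaction_id == "AM"],
                     gi$cell[gi$reaction_id == "AM"])
      expect_true(am[["AM(10)"]] >= am[["AM(1)"]], label = paste("AM", id))
      o2 <- setNames(gi$energy_J_L[gi$reaction_id == "AeMO"],
                     gi$cell[gi$reaction_id == "AeMO"])
      expect_true(o2[["O2(1)"]] >= o2[["O2(0.1)"]], label = paste("O2", id))
    }
  }
})

test_that("pathway ranking is descending with catalog-order ties", {
  springs <- load_seo_fixture()
  springs <- springs[springs$site_type == "spring", ]
  g <- scenario_grid(springs)
  rk <- rank_pathways(g, "Q. Danta")
  expect_true(all(diff(rk$energy_J_L) <= 0))
  # Q. Danta: hydrogenotrophic beats acetoclastic in both acetate scenarios
  e <- setNames(rk$energy_J_L, rk$cell)
  expect_gt(e[["MG"]], e[["AM(10)"]])
  expect_gt(e[["MG"]], e[["AM(1)"]])
  expect_error(rank_pathways(g, "Atlantis"), "Atlantis")
  # all-tied energies keep grid (catalog) order
  tied <- g[g$status == "ok" & g$site_id == "Q. Danta", ]
  tied$energy_J_L <- 0
  expect_equal(rank_pathways(tied, "Q. Danta")$cell, tied$cell)
})

test_that("nitrate-AOM extent at the springs is capped by scarce electron acceptors", {
  springs <- load_seo_fixture()
  springs <- springs[springs$site_type == "spring", ]
  g <- scenario_grid(springs)
  no3 <- g[g$cell == "NO3", ]
  expect_true(all(no3$limiting_species == "NO3-"))
  expect_true(all(no3$extent_umol_L <= 0.2))
  # orders of magnitude below methane availability
  expect_true(all(no3$extent_umol_L < springs$ch4_uM / 100))
})
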