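# Free-energy yield per liter of fluid.
#
# Per-mole Gibbs energies become energy densities by multiplying |dG| by
# the reaction extent allowed by the scarcest reactant:
#   extent (umol/L) = min over limiting candidates of total / |nu|
#   energy (J/L)    = max(0, -dG [kJ/mol]) * extent [umol/L] / 1000
# Limiting totals are measured bulk concentrations (DIC for CO2, NOx-derived
# nitrate, measured CH4/H2) or scenario assumptions (acetate, O2, sulfate),
# not the speciated sub-pools; endergonic reactions clamp to zero yield.

#' Scenario assumptions for unmeasured substrates
#'
#' @param o2_fraction_air_sat Dissolved O2 as a fraction of air-saturation
#'   solubility (the study brackets 0.001 and 0.01, i.e. 0.1% and 1%).
#' @param acetate_fraction_doc Acetate as a fraction of measured DOC
#'   (brackets 0.01 and 0.10).
#' @param assumed_so4_uM Assumed sulfate, umol/L; `NA` (default) means
#'   sulfate-dependent reactions are not computable and are reported as
#'   skipped rather than silently given an invented value.
#' @param acetate_basis `"carbon"` (default: fraction of DOC carbon, i.e.
#'   `fraction * DOC / 2` umol acetate per liter, two carbons per acetate)
#'   or `"molar"` (`fraction * DOC`).
#' @param trace_product_uM Nominal concentration assigned to product species
#'   whose measured total is zero or absent (NO2-, HS-), so that ln Q is
#'   defined; default 0.05 umol/L, half the reporting resolution of the
#'   packaged field table. Flagged `assumed` in speciation output.
#' @return List of class `energy_scenario`.
#' @export
energy_scenario <- function(o2_fraction_air_sat = 0.01,
                            acetate_fraction_doc = 0.10,
                            assumed_so4_uM = NA_real_,
                            acetate_basis = c("carbon", "molar"),
                            trace_product_uM = 0.05) {
  acetate_basis <- match.arg(acetate_basis)
  if (o2_fraction_air_sat <= 0 || o2_fraction_air_sat > 1) {
    abort("o2_fraction_air_sat must be in (0, 1]")
  }
  if (acetate_fraction_doc <= 0 || acetate_fraction_doc > 1) {
    abort("acetate_fraction_doc must be in (0, 1]")
  }
  if (!is.na(assumed_so4_uM) && assumed_so4_uM < 0) {
    abort("assumed_so4_uM must be >= 0")
  }
  structure(list(
    o2_fraction_air_sat = o2_fraction_air_sat,
    acetate_fraction_doc = acetate_fraction_doc,
    assumed_so4_uM = assumed_so4_uM,
    acetate_basis = acetate_basis,
    trace_product_uM = trace_product_uM
  ), class = "energy_scenario")
}

# Resolve the limiting-candidate totals (umol/L) for a reaction at a site.
resolve_limiting_totals <- function(r, s, scenario) {
  s <- as.list(s)
  num <- function(f) {
    x <- s[[f]]
    if (is.null(x)) NA_real_ else as.numeric(x)
  }
  one <- function(key, species) {
    switch(key,
      dic_uM = num("dic_uM"),
      ch4_uM = num("ch4_uM"),
      h2_uM = num("h2_uM"),
      no3_from_nox = {
        nox <- num("nox_uM")
        no2 <- num("no2_uM")
        if (is.na(nox)) NA_real_ else max(nox - (if (is.na(no2)) 0 else no2), 0)
      },
      acetate_scenario = scenario_acetate_uM(num("doc_uM"), scenario),
      o2_scenario = scenario$o2_fraction_air_sat *
        air_saturation_o2_uM(num("temperature_C")),
      so4_scenario = {
        so4 <- num("so4_uM")
        if (!is.na(so4)) so4 else scenario$assumed_so4_uM
      },
      abort(sprintf("unknown limiting source key '%s' for species %s", key, species))
    )
  }
  vals <- vapply(names(r$limiting), function(sp) one(r$limiting[[sp]], sp), numeric(1))
  missing <- names(vals)[is.na(vals)]
  if (length(missing) > 0) {
    srcs <- r$limiting[missing]
    abort(sprintf(
      "reaction %s at site %s: no measurement or scenario value for %s (source: %s)",
      r$reaction_id, s$site_id %||% "?", paste(missing, collapse = ", "),
      paste(srcs, collapse = ", ")))
  }
  vals
}

#' Limiting reactant and reaction extent
#'
#' The extent of reaction per liter is capped by the reactant with the
#' smallest availability per stoichiometric unit: `min(total / |nu|)` over
#' the reaction's limiting candidates. Ties resolve to the first candidate
#' in catalog order.
#'
#' @param r A [reaction()].
#' @param totals Named numeric vector, umol/L, one entry per limiting
#'   candidate species of `r`.
#' @return List: `species` (the limiting reactant), `extent_umol_L`.
#' @export
limiting_reactant <- function(r, totals) {
  cand <- names(r$limiting)
  missing <- setdiff(cand, names(totals))
  if (length(missing) > 0) {
    abort(sprintf("no total supplied for limiting candidate(s): %s",
                  paste(missing, collapse = ", ")))
  }
  per_unit <- vapply(cand, function(sp) totals[[sp]] / abs(r$stoichiometry[[sp]]),
                     numeric(1))
  if (anyNA(per_unit)) {
    abort(sprintf("missing measurement for limiting candidate(s): %s",
                  paste(cand[is.na(per_unit)], collapse = ", ")))
  }
  i <- which.min(per_unit)  # first minimum = catalog order tie-break
  list(species = cand[i], extent_umol_L = per_unit[[i]])
}

#' Free-energy yield per liter for one reaction at one site
#'
#' Chains speciation-based dG with the limiting-reactant extent:
#' `energy_J_L = max(0, -dG) * extent / 1000`. Endergonic reactions yield
#' zero energy but their (positive) dG is reported.
#'
#' @param r A [reaction()].
#' @param fluid [speciate()] result for the site under `scenario`.
#' @param s The site row (for limiting totals).
#' @param scenario The [energy_scenario()] used for `fluid`.
#' @return One-row tibble: site/reaction ids, scenario fields, limiting
#'   species, `extent_umol_L`, `dG0_kJ_mol`, `lnQ`, `dG_kJ_mol`,
#'   `energy_J_L`.
#' @export
energy_per_liter <- function(r, fluid, s, scenario = energy_scenario()) {
  en <- delta_g(r, fluid)
  totals <- resolve_limiting_totals(r, s, scenario)
  lim <- limiting_reactant(r, totals)
  tibble::tibble(
    site_id = fluid$site_id,
    reaction_id = r$reaction_id,
    o2_fraction_air_sat = scenario$o2_fraction_air_sat,
    acetate_fraction_doc = scenario$acetate_fraction_doc,
    assumed_so4_uM = scenario$assumed_so4_uM,
    limiting_species = lim$species,
    extent_umol_L = lim$extent_umol_L,
    dG0_kJ_mol = en$dG0_kJ_mol,
    lnQ = en$lnQ,
    dG_kJ_mol = en$dG_kJ_mol,
    energy_J_L = max(0, -en$dG_kJ_mol) * lim$extent_umol_L / 1000
  )
}

#' The seven default scenario cells
#'
#' One cell per bar of the standard pathway comparison: acetoclastic
#' methanogenesis at 1% and 10% of DOC as acetate, hydrogenotrophic
#' methanogenesis, sulfate- and nitrate-coupled anaerobic methane
#' oxidation, and aerobic methane oxidation at 1.0% and 0.1% of
#' air-saturation O2. Only the assumption each pathway depends on is
#' varied; the base scenario supplies everything else.
#'
#' @param base An [energy_scenario()] providing the shared defaults.
#' @param o2_fractions Two O2 air-saturation fractions (low, high).
#' @param acetate_fractions Two DOC-fraction values (low, high).
#' @return Tibble: `cell`, `reaction_id`, `scenario` (list-column).
#' @export
default_scenario_cells <- function(base = energy_scenario(),
                                   o2_fractions = c(0.001, 0.01),
                                   acetate_fractions = c(0.01, 0.10)) {
  mod <- function(...) {
    sc <- base
    args <- list(...)
    sc[names(args)] <- args
    sc
  }
  tibble::tibble(
    cell = c(sprintf("AM(%g)", acetate_fractions * 100), "MG", "SO4", "NO3",
             sprintf("O2(%g)", rev(o2_fractions) * 100)),
    reaction_id = c("AM", "AM", "MG", "AOM_SO4", "AOM_NO3", "AeMO", "AeMO"),
    scenario = list(
      mod(acetate_fraction_doc = acetate_fractions[1]),
      mod(acetate_fraction_doc = acetate_fractions[2]),
      base, base, base,
      mod(o2_fraction_air_sat = o2_fractions[2]),
      mod(o2_fraction_air_sat = o2_fractions[1])
    )
  )
}

#' Energy densities over sites x reactions x scenarios
#'
#' Runs speciation and the energy-per-liter computation for every site and
#' scenario cell. Cells that cannot be computed (e.g. sulfate-dependent
#' reactions with no assumed sulfate) are recorded with `status` set to the
#' error message rather than dropped.
#'
#' @param sites Site tibble.
#' @param catalog Reaction catalog ([default_reaction_catalog()]).
#' @param cells Scenario cells ([default_scenario_cells()]).
#' @param filler_na_cl_mM Na/Cl filler passed to [speciate()].
#' @return Tibble with one row per site x cell, `status` `"ok"` or an
#'   error description (non-ok rows have `NA` energetics).
#' @export
scenario_grid <- function(sites, catalog = default_reaction_catalog(),
                          cells = default_scenario_cells(),
                          filler_na_cl_mM = 12.5) {
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    for (j in seq_len(nrow(cells))) {
      rid <- cells$reaction_id[j]
      sc <- cells$scenario[[j]]
      r <- catalog[[rid]]
      if (is.null(r)) {
        abort(sprintf("reaction '%s' not in catalog", rid))
      }
      row <- tryCatch({
        fl <- speciate(s, filler_na_cl_mM, sc)
        out <- energy_per_liter(r, fl, s, sc)
        out$cell <- cells$cell[j]
        out$status <- "ok"
        out
      }, error = function(e) {
        tibble::tibble(
          site_id = s$site_id, reaction_id = rid,
          o2_fraction_air_sat = sc$o2_fraction_air_sat,
          acetate_fraction_doc = sc$acetate_fraction_doc,
          assumed_so4_uM = sc$assumed_so4_uM,
          limiting_species = NA_character_, extent_umol_L = NA_real_,
          dG0_kJ_mol = NA_real_, lnQ = NA_real_, dG_kJ_mol = NA_real_,
          energy_J_L = NA_real_, cell = cells$cell[j],
          status = conditionMessage(e))
      })
      rows[[length(rows) + 1]] <- row
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      site_id = character(), cell = character(), reaction_id = character(),
      status = character(), o2_fraction_air_sat = numeric(),
      acetate_fraction_doc = numeric(), assumed_so4_uM = numeric(),
      limiting_species = character(), extent_umol_L = numeric(),
      dG0_kJ_mol = numeric(), lnQ = numeric(), dG_kJ_mol = numeric(),
      energy_J_L = numeric()))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::relocate(out, "site_id", "cell", "reaction_id", "status")
}

#' Rank pathways at a site by energy yield
#'
#' @param results A [scenario_grid()] tibble.
#' @param site_id Site to rank.
#' @return The site's `ok` rows ordered by decreasing `energy_J_L`; the
#'   sort is stable, so tied rows (e.g. all-zero energies) keep catalog
#'   order. Skipped cells are excluded.
#' @export
rank_pathways <- function(results, site_id) {
  sub <- results[results$site_id == site_id, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(sprintf("no results for site '%s'", site_id))
  }
  ok <- sub[sub$status == "ok", , drop = FALSE]
  ok[order(-ok$energy_J_L), ]
}
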