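# Pipeline drivers: run a full analysis stage, write machine-readable
# outputs plus a provenance block, and return the in-memory results.
# The numbered scripts under analysis/ are thin wrappers over these.

write_provenance <- function(out_dir, stage, config) {
  prov <- c(list(stage = stage, package_version = as.character(utils::packageVersion("serpenergy")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), config)
  jsonlite::write_json(prov, file.path(out_dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
}

#' Run the full energetics pipeline
#'
#' Speciates every site, evaluates the scenario grid of energy densities,
#' ranks pathways per site, and writes speciation, energetics, and ranking
#' tables (CSV) plus a provenance block to `out_dir`. Sulfate-dependent
#' cells are reported as skipped (with the reason in `status`) unless an
#' assumed sulfate concentration is supplied.
#'
#' @param sites Site tibble (default: the packaged field fixture).
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing files.
#' @param base_scenario Shared scenario defaults ([energy_scenario()]).
#' @param o2_fractions,acetate_fractions Scenario brackets for the grid.
#' @param filler_na_cl_mM Na/Cl filler for speciation.
#' @param site_types Which site types to run the energetics grid on
#'   (default `"spring"`; speciation output covers all sites).
#' @return List: `speciation` (long tibble over all sites), `energetics`
#'   (the [scenario_grid()] tibble), `rankings` (per-site ordered tibble).
#' @export
run_energetics <- function(sites = load_seo_fixture(), out_dir = NULL,
                           base_scenario = energy_scenario(),
                           o2_fractions = c(0.001, 0.01),
                           acetate_fractions = c(0.01, 0.10),
                           filler_na_cl_mM = 12.5,
                           site_types = "spring") {
  bad <- validate_sites(sites)
  if (nrow(bad) > 0) {
    abort(sprintf("input table fails validation: %s",
                  paste(unique(bad$violation), collapse = "; ")))
  }
  spec_rows <- purrr::map(seq_len(nrow(sites)), function(i) {
    tryCatch(speciation_long(speciate(sites[i, ], filler_na_cl_mM, base_scenario)),
             error = function(e) {
               warn(sprintf("speciation skipped for %s: %s",
                            sites$site_id[i], conditionMessage(e)))
               NULL
             })
  })
  speciation <- dplyr::bind_rows(spec_rows)
  grid_sites <- sites[sites$site_type %in% site_types, , drop = FALSE]
  cells <- default_scenario_cells(base_scenario, o2_fractions, acetate_fractions)
  energetics <- scenario_grid(grid_sites, default_reaction_catalog(), cells,
                              filler_na_cl_mM)
  skipped <- energetics[energetics$status != "ok", ]
  if (nrow(skipped) > 0) {
    warn(sprintf("%d grid cell(s) skipped: %s", nrow(skipped),
                 paste(unique(skipped$status), collapse = " | ")))
  }
  rankings <- dplyr::bind_rows(
    lapply(unique(grid_sites$site_id), function(id) rank_pathways(energetics, id)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(speciation, file.path(out_dir, "speciation.csv"), progress = FALSE)
    readr::write_csv(energetics, file.path(out_dir, "energy_density.csv"), progress = FALSE)
    readr::write_csv(rankings, file.path(out_dir, "pathway_rankings.csv"), progress = FALSE)
    write_provenance(out_dir, "energetics", list(
      n_sites = nrow(sites), site_types = site_types,
      filler_na_cl_mM = filler_na_cl_mM,
      o2_fractions = o2_fractions, acetate_fractions = acetate_fractions,
      acetate_basis = base_scenario$acetate_basis,
      assumed_so4_uM = base_scenario$assumed_so4_uM,
      trace_product_uM = base_scenario$trace_product_uM))
  }
  list(speciation = speciation, energetics = energetics, rankings = rankings)
}

#' Grouped bar chart of energy densities
#'
#' One panel per site, one bar per scenario cell, bar height the
#' free-energy yield in J per liter of fluid.
#'
#' @param energetics A [scenario_grid()] tibble.
#' @return A ggplot object.
#' @export
plot_energy_density <- function(energetics) {
  ok <- energetics[energetics$status == "ok", ]
  ok$cell <- factor(ok$cell, levels = unique(energetics$cell))
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$cell, y = .data$energy_J_L,
                                   fill = .data$reaction_id)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~site_id) +
    ggplot2::labs(x = NULL, y = "Free-energy yield (J per L of fluid)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Run the methane-cycler guild screen
#'
#' @param tab Taxonomy tibble or path to a TSV readable by
#'   [read_taxonomy_table()].
#' @param out_dir Output directory; `NULL` to skip writing.
#' @param guilds Guild lists.
#' @param domain `"Archaea"` or `"Bacteria"`.
#' @param groups Optional sample grouping for [guild_summary()].
#' @return List: `screen` (the [screen_methane_cyclers()] result),
#'   `summary` (the [guild_summary()] tibble).
#' @export
run_screen <- function(tab, out_dir = NULL, guilds = default_guild_lists(),
                       domain = "Archaea", groups = NULL) {
  if (is.character(tab)) tab <- read_taxonomy_table(tab)
  if (nrow(tab) == 0) abort("no samples: taxonomy table is empty")
  screen <- screen_methane_cyclers(tab, guilds, domain)
  summ <- guild_summary(screen, groups)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(screen$fractions, file.path(out_dir, "guild_fractions.csv"),
                     progress = FALSE)
    jsonlite::write_json(screen$inventory,
                         file.path(out_dir, "matched_lineages.json"),
                         dataframe = "rows", pretty = TRUE)
    readr::write_csv(summ, file.path(out_dir, "guild_summary.csv"), progress = FALSE)
    write_provenance(out_dir, "screen", list(domain = domain))
  }
  list(screen = screen, summary = summ)
}

#' Generate and write synthetic fluid + taxonomy tables
#'
#' @param out_dir Output directory; `NULL` to skip writing.
#' @param fluid_params A [fluid_sim_params()].
#' @param tax_params A [tax_sim_params()]; defaults to spring-like archaeal
#'   communities whose combined methanogen + ANME target fractions span
#'   0.4-0.9, the band observed in hyperalkaline spring fluids.
#' @param seed Integer seed overriding the seeds in both parameter objects.
#' @return List: `fluids` (from [simulate_fluid_table()]), `taxonomy`
#'   (from [simulate_taxonomy_table()]).
#' @export
run_simulate <- function(out_dir = NULL, fluid_params = fluid_sim_params(),
                         tax_params = NULL, seed = NULL) {
  if (!is.null(seed)) fluid_params$seed <- as.integer(seed)
  if (is.null(tax_params)) {
    combined <- seq(0.4, 0.9, length.out = 6)
    tax_params <- tax_sim_params(
      targets = tibble::tibble(
        sample_id = sprintf("SYN-SPRING-%02d", seq_along(combined)),
        methanogen = combined * 0.5,
        anme = combined * 0.5),
      seed = (fluid_params$seed %||% 1L) + 1L)
  }
  if (!is.null(seed)) tax_params$seed <- as.integer(seed) + 1L
  fluids <- simulate_fluid_table(fluid_params)
  taxonomy <- simulate_taxonomy_table(tax_params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_site_table(fluids$samples, file.path(out_dir, "synthetic_fluids.csv"))
    write_taxonomy_table(taxonomy$table, file.path(out_dir, "synthetic_taxonomy.tsv"))
    jsonlite::write_json(
      list(fluid_truth = fluids$truth[c("n_spring", "n_background", "spring", "background", "seed")],
           taxonomy_truth = taxonomy$truth),
      file.path(out_dir, "synthetic_truth.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_provenance(out_dir, "simulate",
                     list(fluid_seed = fluid_params$seed, tax_seed = tax_params$seed))
  }
  list(fluids = fluids, taxonomy = taxonomy)
}
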