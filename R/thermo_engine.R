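# Standard-state thermodynamics for the catabolic reaction catalog.
#
# An embedded table of aqueous species carries standard Gibbs energies and
# enthalpies of formation at 25 C / 1 bar from the standard SUPCRT-consistent
# compilations (sources cited per entry in the data file). dG0 at in-situ
# temperature uses the Gibbs-Helmholtz / van 't Hoff correction with constant
# dH0, which over the 24-30 C range of these fluids introduces << 1 kJ/mol
# of error. In-situ Gibbs energies follow dG = dG0 + RT ln Q with activities
# from the speciation module.

#' Embedded standard-state species table
#'
#' @return Tibble with columns `species`, `formula`, `charge`,
#'   `dGf_25C_kJ_mol`, `dHf_25C_kJ_mol`, `phase`, `source`.
#' @export
thermo_species_table <- function() {
  if (is.null(the_cache$thermo_species)) {
    tab <- readr::read_csv(pkg_extdata("thermo_species.csv"),
                           col_types = readr::cols(
                             species = readr::col_character(),
                             formula = readr::col_character(),
                             charge = readr::col_integer(),
                             dGf_25C_kJ_mol = readr::col_double(),
                             dHf_25C_kJ_mol = readr::col_double(),
                             phase = readr::col_character(),
                             source = readr::col_character()
                           ), progress = FALSE)
    the_cache$thermo_species <- tab
  }
  the_cache$thermo_species
}

# "C2H3O2" -> c(C = 2, H = 3, O = 2)
parse_formula <- function(formula) {
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0 || paste(parts, collapse = "") != formula) {
    abort(sprintf("cannot parse chemical formula '%s'", formula))
  }
  elems <- sub("[0-9]*$", "", parts)
  counts <- as.numeric(ifelse(grepl("[0-9]+$", parts),
                              sub("^[A-Za-z]+", "", parts), "1"))
  tapply(counts, elems, sum)
}

#' Construct a catabolic reaction
#'
#' @param reaction_id Short identifier (e.g. `"MG"`).
#' @param name Display name.
#' @param category One of `"methanogenesis"`, `"anaerobic_methanotrophy"`,
#'   `"aerobic_methanotrophy"`, or `"dissociation"` (internal equilibria).
#' @param stoichiometry Named numeric vector of signed coefficients
#'   (reactants negative, products positive), named by species label.
#' @param limiting Named character vector mapping reactant species to the
#'   measurement or scenario key that quantifies their availability.
#' @return Object of class `catabolic_reaction`.
#' @export
reaction <- function(reaction_id, name, category, stoichiometry, limiting = character()) {
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  structure(list(reaction_id = reaction_id, name = name, category = category,
                 stoichiometry = stoichiometry, limiting = limiting),
            class = "catabolic_reaction")
}

#' @export
print.catabolic_reaction <- function(x, ...) {
  st <- x$stoichiometry
  lhs <- st[st < 0]; rhs <- st[st > 0]
  fmt <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                  paste0(abs(v), " ", names(v))), collapse = " + ")
  cat(sprintf("<%s> %s [%s]\n  %s -> %s\n", x$reaction_id, x$name, x$category,
              fmt(lhs), fmt(rhs)))
  invisible(x)
}

#' The default methane-cycling reaction catalog
#'
#' Five reactions: hydrogenotrophic methanogenesis (MG), acetoclastic
#' methanogenesis (AM), anaerobic methane oxidation coupled to sulfate
#' (AOM_SO4) or nitrate (AOM_NO3) reduction, and aerobic methane oxidation
#' (AeMO). Bicarbonate is the inorganic-carbon product of the oxidation
#' reactions (the dominant carbonate species at circumneutral to alkaline
#' pH); MG consumes dissolved CO2. The catalog ships as an editable CSV so
#' alternative electron-acceptor products can be substituted.
#'
#' @return Named list of [reaction()] objects, in catalog order.
#' @export
default_reaction_catalog <- function() {
  if (is.null(the_cache$catalog)) {
    tab <- readr::read_csv(pkg_extdata("reaction_catalog.csv"),
                           col_types = readr::cols(
                             reaction_id = readr::col_character(),
                             name = readr::col_character(),
                             category = readr::col_character(),
                             species = readr::col_character(),
                             coefficient = readr::col_double(),
                             limiting_source = readr::col_character()
                           ), progress = FALSE)
    ids <- unique(tab$reaction_id)
    catalog <- lapply(ids, function(id) {
      rows <- tab[tab$reaction_id == id, ]
      st <- setNames(rows$coefficient, rows$species)
      lim_rows <- rows[!is.na(rows$limiting_source) & nzchar(rows$limiting_source), ]
      lim <- setNames(lim_rows$limiting_source, lim_rows$species)
      reaction(id, rows$name[1], rows$category[1], st, lim)
    })
    names(catalog) <- ids
    for (r in catalog) {
      bad <- check_balance(r)
      if (length(bad) > 0) {
        abort(sprintf("packaged catalog reaction %s is unbalanced: %s",
                      r$reaction_id, paste(bad, collapse = "; ")))
      }
    }
    the_cache$catalog <- catalog
  }
  the_cache$catalog
}

#' Check element and charge balance of a reaction
#'
#' @param r A [reaction()].
#' @param species_table Species table (defaults to the embedded one).
#' @return Character vector of violations (empty if balanced).
#' @export
check_balance <- function(r, species_table = thermo_species_table()) {
  st <- r$stoichiometry
  unknown <- setdiff(names(st), species_table$species)
  if (length(unknown) > 0) {
    abort(sprintf("unknown species in reaction %s: %s", r$reaction_id,
                  paste(unknown, collapse = ", ")))
  }
  elem_sum <- list()
  charge_sum <- 0
  for (sp in names(st)) {
    row <- species_table[species_table$species == sp, ]
    counts <- parse_formula(row$formula)
    for (e in names(counts)) {
      elem_sum[[e]] <- (elem_sum[[e]] %||% 0) + st[[sp]] * counts[[e]]
    }
    charge_sum <- charge_sum + st[[sp]] * row$charge
  }
  v <- character()
  for (e in names(elem_sum)) {
    if (abs(elem_sum[[e]]) > 1e-9) {
      v <- c(v, sprintf("element %s imbalance: %+g", e, elem_sum[[e]]))
    }
  }
  if (abs(charge_sum) > 1e-9) {
    v <- c(v, sprintf("charge imbalance: %+g", charge_sum))
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard Gibbs energy of reaction at temperature
#'
#' dG0(298.15 K) is the stoichiometric sum of formation energies;
#' temperature correction by Gibbs-Helmholtz with constant dH0:
#' `dG0(T) = dG0(T0) * T/T0 + dH0(T0) * (1 - T/T0)`, T0 = 298.15 K.
#' Valid over roughly 283-333 K, the window within which the constant-dH0
#' approximation stays well under 1 kJ/mol for these reactions.
#'
#' @param r A [reaction()].
#' @param T_K Temperature in kelvin.
#' @param species_table Species table.
#' @return dG0 in kJ/mol.
#' @export
delta_g_standard <- function(r, T_K, species_table = thermo_species_table()) {
  if (T_K <= 283 || T_K >= 333) {
    abort(sprintf("T = %.2f K outside the 283-333 K validity window", T_K))
  }
  st <- r$stoichiometry
  idx <- match(names(st), species_table$species)
  if (anyNA(idx)) {
    abort(sprintf("unknown species: %s",
                  paste(names(st)[is.na(idx)], collapse = ", ")))
  }
  dG0 <- sum(st * species_table$dGf_25C_kJ_mol[idx])
  dH0 <- sum(st * species_table$dHf_25C_kJ_mol[idx])
  tau <- T_K / T_REF_K
  dG0 * tau + dH0 * (1 - tau)
}

#' Activity quotient of a reaction in a speciated fluid
#'
#' `ln Q = sum(nu_i * ln a_i)` with the dilute-solution conventions
#' `a(H2O) = 1` and `a(H+) = 10^-pH` (taken from the fluid).
#'
#' @param r A [reaction()].
#' @param fluid A [speciate()] result.
#' @return `ln Q` (unitless).
#' @export
activity_quotient <- function(r, fluid) {
  st <- r$stoichiometry
  lnQ <- 0
  for (sp in names(st)) {
    nu <- st[[sp]]
    if (sp == "H2O") next
    if (sp == "H+") {
      a <- 10^(-fluid$pH)
    } else {
      i <- match(sp, fluid$species$species)
      a <- if (is.na(i)) NA_real_ else fluid$species$activity[i]
    }
    if (is.na(a) || a <= 0) {
      abort(sprintf("species %s has zero or missing activity at site %s",
                    sp, fluid$site_id))
    }
    lnQ <- lnQ + nu * log(a)
  }
  lnQ
}

#' In-situ Gibbs energy of a reaction
#'
#' Evaluates `dG = dG0(T) + R T ln Q / 1000` (kJ/mol) at the fluid's
#' temperature, with activities from the speciation result. Negative dG
#' means the reaction as written is exergonic.
#'
#' @param r A [reaction()].
#' @param fluid A [speciate()] result.
#' @return One-row tibble: `reaction_id`, `temperature_K`, `dG0_kJ_mol`,
#'   `lnQ`, `dG_kJ_mol`.
#' @export
delta_g <- function(r, fluid) {
  T_K <- fluid$temperature_K
  dG0 <- delta_g_standard(r, T_K)
  lnQ <- activity_quotient(r, fluid)
  tibble::tibble(
    reaction_id = r$reaction_id,
    temperature_K = T_K,
    dG0_kJ_mol = dG0,
    lnQ = lnQ,
    dG_kJ_mol = dG0 + R_GAS_J_MOL_K * T_K * lnQ / 1000
  )
}

#' Reverse a reaction
#'
#' @param r A [reaction()].
#' @return The reaction with all stoichiometric coefficients negated.
#' @export
reverse_reaction <- function(r) {
  reaction(paste0(r$reaction_id, "_rev"), paste(r$name, "(reversed)"),
           r$category, -r$stoichiometry, r$limiting)
}
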