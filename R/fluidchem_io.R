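# Site fluid-geochemistry tables: schema, readers/writers, validation,
# and range summaries. One row per sampling site; concentrations in umol/L,
# below-detection cells ("bdl" or empty) stored as NA.

SITE_TYPES <- c("spring", "river", "well")

# canonical column order; everything except the first two is numeric
SITE_FIELDS <- c(
  "site_id", "site_type", "temperature_C", "pH", "conductivity_uS_cm",
  "tds_ppm", "salinity_ppm", "orp_mV", "doc_uM", "dic_uM", "d13C_CO2_permil",
  "tdn_uM", "nox_uM", "no2_uM", "nh4_uM", "don_uM", "po4_uM", "tdp_uM",
  "ch4_uM", "d13C_CH4_permil", "h2_uM", "d18O_permil", "d2H_permil", "so4_uM"
)

SITE_REQUIRED <- c(
  "site_id", "site_type", "temperature_C", "pH",
  "dic_uM", "doc_uM", "ch4_uM", "h2_uM"
)

# concentration-like fields that must be >= 0 when non-missing
SITE_CONC_FIELDS <- c(
  "conductivity_uS_cm", "tds_ppm", "salinity_ppm", "doc_uM", "dic_uM",
  "tdn_uM", "nox_uM", "no2_uM", "nh4_uM", "don_uM", "po4_uM", "tdp_uM",
  "ch4_uM", "h2_uM", "so4_uM"
)

SITE_NA_TOKENS <- c("", "NA", "bdl", "BDL", "Bdl", "nd", "ND")

#' Column dialect for site tables
#'
#' Maps the canonical column names used throughout the package onto the
#' headers of a particular file, optionally with multiplicative scale
#' factors to convert concentration units (e.g. `mM` tables to `uM`).
#'
#' @param columns Named character vector, `canonical_name = "file header"`.
#'   Defaults to the identity mapping over the canonical schema.
#' @param scale Named numeric vector of multipliers applied after parsing,
#'   named by canonical column (e.g. `c(dic_uM = 1000)` for a table in mM).
#' @return A list of class `site_dialect`.
#' @export
site_dialect <- function(columns = NULL, scale = NULL) {
  full <- setNames(SITE_FIELDS, SITE_FIELDS)
  if (!is.null(columns)) {
    bad <- setdiff(names(columns), SITE_FIELDS)
    if (length(bad) > 0) {
      abort(sprintf("unknown canonical column(s) in dialect: %s",
                    paste(bad, collapse = ", ")))
    }
    full[names(columns)] <- columns
  }
  structure(list(columns = full, scale = scale), class = "site_dialect")
}

parse_numeric_cell <- function(x, row, column) {
  x <- trimws(x)
  if (is.na(x) || x %in% SITE_NA_TOKENS) return(NA_real_)
  val <- suppressWarnings(as.numeric(x))
  if (is.na(val)) {
    abort(sprintf("non-numeric value '%s' in column '%s', data row %d",
                  x, column, row))
  }
  val
}

#' Read a site fluid-geochemistry table
#'
#' Reads a delimited text table (CSV, header row, decimal point) with one
#' row per site. Cells that are empty or read "bdl" (below detection limit)
#' become `NA`.
#'
#' @param path File to read.
#' @param dialect A [site_dialect()] mapping canonical columns to headers.
#' @return A tibble with the canonical site columns (one row per site).
#' @export
read_site_table <- function(path, dialect = site_dialect()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  cols <- dialect$columns
  missing_req <- SITE_REQUIRED[!cols[SITE_REQUIRED] %in% names(raw)]
  if (length(missing_req) > 0) {
    abort(sprintf("required column(s) missing from %s: %s",
                  path, paste(cols[missing_req], collapse = ", ")))
  }
  numeric_fields <- setdiff(SITE_FIELDS, c("site_id", "site_type"))
  n <- nrow(raw)
  out <- tibble::tibble(
    site_id = trimws(as.character(raw[[cols[["site_id"]]]])),
    site_type = tolower(trimws(as.character(raw[[cols[["site_type"]]]])))
  )
  for (f in numeric_fields) {
    src <- cols[[f]]
    if (src %in% names(raw)) {
      vals <- vapply(seq_len(n), function(i) parse_numeric_cell(raw[[src]][i], i, src),
                     numeric(1))
    } else {
      vals <- rep(NA_real_, n)
    }
    if (!is.null(dialect$scale) && f %in% names(dialect$scale)) {
      vals <- vals * dialect$scale[[f]]
    }
    out[[f]] <- vals
  }
  if (anyDuplicated(out$site_id)) {
    dup <- unique(out$site_id[duplicated(out$site_id)])
    abort(sprintf("duplicate site_id: %s", paste(dup, collapse = ", ")))
  }
  out[SITE_FIELDS]
}

#' Write a site table back to CSV
#'
#' Inverse of [read_site_table()]: `NA` cells are written empty, numeric
#' values as shortest round-trip decimal text.
#'
#' @param sites Site tibble as returned by [read_site_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  readr::write_csv(sites, path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate a single site record
#'
#' Checks the schema invariants: pH in (0, 14), temperature in (0, 60) C,
#' nonnegative concentrations, and a recognised site type. Violations are
#' returned as data, not raised.
#'
#' @param s A one-row site tibble, or a named list with site fields.
#' @return Character vector of violation descriptions (empty if valid).
#' @export
validate_sample <- function(s) {
  s <- as.list(s)
  v <- character()
  chk <- function(cond, msg) if (isTRUE(cond)) c(v, msg) else v
  if (!is.null(s$site_type) && !is.na(s$site_type)) {
    v <- chk(!(s$site_type %in% SITE_TYPES),
             sprintf("site_type '%s' not one of %s", s$site_type,
                     paste(SITE_TYPES, collapse = "/")))
  } else {
    v <- c(v, "site_type missing")
  }
  num <- function(f) if (is.null(s[[f]])) NA_real_ else as.numeric(s[[f]])
  pH <- num("pH")
  if (!is.na(pH) && (pH <= 0 || pH >= 14)) {
    v <- c(v, sprintf("pH %.2f outside (0, 14)", pH))
  }
  tc <- num("temperature_C")
  if (!is.na(tc) && (tc <= 0 || tc >= 60)) {
    v <- c(v, sprintf("temperature_C %.1f outside (0, 60)", tc))
  }
  for (f in SITE_CONC_FIELDS) {
    x <- num(f)
    if (!is.na(x) && x < 0) {
      v <- c(v, sprintf("%s = %g is negative", f, x))
    }
  }
  v
}

#' Validate every row of a site table
#'
#' @param sites Site tibble.
#' @return Tibble with columns `site_id`, `violation` (zero rows if clean).
#'   Duplicate `site_id`s are reported as violations too.
#' @export
validate_sites <- function(sites) {
  rows <- purrr::map(seq_len(nrow(sites)), function(i) {
    v <- validate_sample(sites[i, ])
    if (length(v) == 0) return(NULL)
    tibble::tibble(site_id = sites$site_id[i], violation = v)
  })
  out <- dplyr::bind_rows(rows)
  dup <- unique(sites$site_id[duplicated(sites$site_id)])
  if (length(dup) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      site_id = dup, violation = "duplicate site_id"))
  }
  if (nrow(out) == 0) tibble::tibble(site_id = character(), violation = character()) else out
}

#' The packaged Santa Elena Ophiolite fluid-chemistry fixture
#'
#' Nine sites (three hyperalkaline springs, three rivers, three groundwater
#' wells) sampled during the February 2014 dry-season campaign, with pH,
#' temperature, conductivity, redox potential, carbon, nitrogen and
#' phosphorus species, dissolved methane and hydrogen, and stable-isotope
#' values. Sulfate was not measured and is `NA` throughout; analyses
#' requiring it must supply an assumed value explicitly.
#'
#' @return Site tibble with 9 rows.
#' @export
load_seo_fixture <- function() {
  if (is.null(the_cache$seo_fixture)) {
    the_cache$seo_fixture <- read_site_table(pkg_extdata("seo_table1.csv"))
  }
  the_cache$seo_fixture
}

#' Summarise a numeric field over a subset of sites
#'
#' Computes count, min, max, and mean of the non-missing values of `field`,
#' optionally restricted by `site_type` or an arbitrary row predicate.
#'
#' @param sites Site tibble.
#' @param field Name of a numeric site column.
#' @param site_type Optional site type (`"spring"`, `"river"`, `"well"`).
#' @param predicate Optional function `sites -> logical` row filter,
#'   applied after the `site_type` filter.
#' @return One-row tibble: `field`, `predicate`, `count`, `min`, `max`, `mean`.
#'   `min`/`max`/`mean` are `NA` when no non-missing values remain.
#' @export
summarize_sites <- function(sites, field, site_type = NULL, predicate = NULL) {
  numeric_fields <- setdiff(SITE_FIELDS, c("site_id", "site_type"))
  if (!field %in% numeric_fields) {
    abort(sprintf("unknown numeric field '%s'; valid fields: %s",
                  field, paste(numeric_fields, collapse = ", ")))
  }
  label <- "all"
  if (!is.null(site_type)) {
    sites <- sites[sites$site_type %in% site_type, , drop = FALSE]
    label <- paste(site_type, collapse = "|")
  }
  if (!is.null(predicate)) {
    keep <- predicate(sites)
    sites <- sites[keep, , drop = FALSE]
    label <- paste0(label, "+predicate")
  }
  x <- sites[[field]]
  x <- x[!is.na(x)]
  tibble::tibble(
    field = field, predicate = label, count = length(x),
    min = if (length(x)) min(x) else NA_real_,
    max = if (length(x)) max(x) else NA_real_,
    mean = if (length(x)) mean(x) else NA_real_
  )
}
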