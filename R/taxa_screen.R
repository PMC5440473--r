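# Methane-cycler guild screen over classified 16S taxon-abundance tables.
#
# Lineages (semicolon-ranked text, mothur/SILVA style) are matched against
# curated lists of aerobic methanotroph genera, NC10 methanotrophs,
# methanogen orders, and ANME clade labels; per-sample relative abundances
# are computed against the per-domain read total (archaeal fractions over
# archaeal reads, bacterial over bacterial), mirroring separate
# domain-specific amplicon datasets.

#' Default methane-cycler guild lists
#'
#' Aerobic methanotroph genera of the Methylococcaceae, Methylocystaceae,
#' Beijerinckiaceae and Verrucomicrobia; the NC10 methanotrophs
#' (Ca. Methylomirabilis); the seven methanogen orders; and ANME clade
#' labels. The genus list keeps the historical misspelling "Methyothermus"
#' alongside the standard spelling "Methylothermus" so either form is
#' recognised. Lineages matching an ANME label (including Methanoperedens,
#' the ANME-2d clade that nests inside Methanosarcinales) are assigned to
#' the ANME guild and never double-counted as methanogens.
#'
#' @return List of class `guild_lists`: `methanotroph_genera`,
#'   `nc10_labels`, `methanogen_orders`, `anme_labels`.
#' @export
default_guild_lists <- function() {
  structure(list(
    methanotroph_genera = c(
      "Methylococcus", "Methylocaldum", "Methylohalobius", "Methyothermus",
      "Methylothermus", "Methylobacter", "Methylomicrobium", "Methylomonas",
      "Methylosarcina", "Methylosoma", "Methylosphaera", "Crenothrix",
      "Clonothrix", "Methylocystis", "Methylosinus", "Methylocella",
      "Methylocapsa", "Methylacidiphilum"),
    nc10_labels = c("Methylomirabilis", "NC10"),
    methanogen_orders = c(
      "Methanopyrales", "Methanococcales", "Methanobacteriales",
      "Methanomicrobiales", "Methanocellales", "Methanoplasmatales",
      "Methanosarcinales"),
    anme_labels = c(
      "ANME-1", "ANME-1a", "ANME-1b", "ANME-2", "ANME-2a", "ANME-2b",
      "ANME-2c", "ANME-2d", "ANME-3", "Methanoperedens")
  ), class = "guild_lists")
}

# normalize one lineage rank token for matching
normalize_rank <- function(x) {
  x <- gsub('["\']', "", trimws(x))
  x <- sub("\\([0-9]+\\)$", "", x)           # mothur bootstrap confidence
  x <- sub("^(Candidatus[_ ]|Ca\\.?[_ ])", "", x, ignore.case = TRUE)
  x <- gsub("_", " ", x)
  trimws(tolower(x))
}

split_lineage <- function(lineage) {
  ranks <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  ranks <- ranks[nzchar(trimws(ranks))]
  vapply(ranks, normalize_rank, character(1), USE.NAMES = FALSE)
}

# classify one lineage -> guild label or NA; rank-aware:
# genera at rank 6, orders at rank 4, ANME/NC10 labels at any rank.
classify_lineage <- function(ranks, g) {
  anme <- normalize_rank(g$anme_labels)
  if (any(ranks %in% anme) || any(grepl("^anme", ranks))) return("anme")
  nc10 <- normalize_rank(g$nc10_labels)
  if (any(ranks %in% nc10)) return("methanotroph_nc10")
  orders <- normalize_rank(g$methanogen_orders)
  order_rank <- if (length(ranks) >= 4) ranks[4] else NA_character_
  if (!is.na(order_rank) && order_rank %in% orders) return("methanogen")
  # short lineages: accept an order name at the terminal rank
  if (length(ranks) < 4 && length(ranks) > 0 && ranks[length(ranks)] %in% orders) {
    return("methanogen")
  }
  genera <- normalize_rank(g$methanotroph_genera)
  genus_rank <- if (length(ranks) >= 6) ranks[6] else NA_character_
  if (!is.na(genus_rank) && genus_rank %in% genera) return("methanotroph_bacteria")
  if (length(ranks) >= 1 && ranks[length(ranks)] %in% genera) {
    return("methanotroph_bacteria")
  }
  NA_character_
}

#' Read a classified taxon-abundance table
#'
#' Expects a TSV with a `lineage` column (semicolon-ranked taxonomy text)
#' and one integer count column per sample.
#'
#' @param path File to read.
#' @return Tibble: `lineage` plus one numeric column per sample.
#' @export
read_taxonomy_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (!"lineage" %in% header) {
    abort(sprintf("no 'lineage' column in %s", path))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    lineage = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  if (ncol(tab) < 2) abort(sprintf("no sample count columns in %s", path))
  bad <- which(vapply(tab[-1], function(x) any(is.na(x) | x < 0), logical(1)))
  if (length(bad) > 0) {
    abort(sprintf("negative or missing counts in sample column(s): %s",
                  paste(names(tab[-1])[bad], collapse = ", ")))
  }
  tab
}

#' Write a taxonomy table to TSV
#'
#' @param tab Taxonomy tibble (as from [read_taxonomy_table()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_taxonomy_table <- function(tab, path) {
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Screen a taxonomy table for methane-cycling guilds
#'
#' Classifies each lineage into a guild (aerobic methanotroph bacteria,
#' NC10, methanogen, ANME) and computes per-sample relative abundances as
#' matched counts over the total counts assigned to `domain` (first lineage
#' rank). Samples with zero reads in the domain get `NA` fractions.
#'
#' @param tab Taxonomy tibble: `lineage` + one count column per sample.
#' @param guilds A [default_guild_lists()] object.
#' @param domain `"Archaea"` or `"Bacteria"`.
#' @return List of class `methane_screen`: `fractions` (tibble, one row per
#'   sample: `sample_id`, `domain_reads`, `methanotroph_bacteria`,
#'   `methanotroph_nc10`, `methanogen`, `anme`, `methane_cycler` =
#'   methanogen + anme), and `inventory` (tibble of matched lineages with
#'   their guild).
#' @export
screen_methane_cyclers <- function(tab, guilds = default_guild_lists(),
                                   domain = c("Archaea", "Bacteria")) {
  domain <- match.arg(domain)
  sample_ids <- setdiff(names(tab), "lineage")
  ranks_list <- lapply(tab$lineage, split_lineage)
  in_domain <- vapply(ranks_list, function(r) {
    length(r) > 0 && r[1] == tolower(domain)
  }, logical(1))
  guild <- rep(NA_character_, nrow(tab))
  guild[in_domain] <- vapply(ranks_list[in_domain], classify_lineage,
                             character(1), g = guilds)
  counts <- as.matrix(tab[sample_ids])
  domain_tot <- colSums(counts[in_domain, , drop = FALSE])
  guild_levels <- c("methanotroph_bacteria", "methanotroph_nc10",
                    "methanogen", "anme")
  frac <- sapply(guild_levels, function(gl) {
    hit <- !is.na(guild) & guild == gl
    colSums(counts[hit, , drop = FALSE]) / ifelse(domain_tot > 0, domain_tot, NA)
  })
  frac <- matrix(frac, ncol = length(guild_levels),
                 dimnames = list(sample_ids, guild_levels))
  fractions <- tibble::as_tibble(frac, rownames = "sample_id")
  fractions$domain_reads <- as.numeric(domain_tot)
  fractions$methane_cycler <- fractions$methanogen + fractions$anme
  fractions <- dplyr::relocate(fractions, "sample_id", "domain_reads")
  if (all(domain_tot == 0)) {
    warn(sprintf("no reads assigned to domain %s in any sample", domain))
  }
  inventory <- tibble::tibble(lineage = tab$lineage, guild = guild)
  inventory <- inventory[!is.na(inventory$guild), ]
  structure(list(fractions = fractions, inventory = inventory,
                 domain = domain), class = "methane_screen")
}

#' Per-group range of the combined methane-cycler fraction
#'
#' Summarises the methanogen + ANME fraction (the "methane cycler" share of
#' the domain's reads) as min and max within each sample group.
#'
#' @param screen A [screen_methane_cyclers()] result.
#' @param groups Named character/factor vector mapping `sample_id` to a
#'   group label; defaults to one group containing every sample.
#' @return Tibble: `group`, `n_samples`, `min_fraction`, `max_fraction`.
#' @export
guild_summary <- function(screen, groups = NULL) {
  fr <- screen$fractions
  if (is.null(groups)) {
    groups <- setNames(rep("all", nrow(fr)), fr$sample_id)
  }
  miss <- setdiff(fr$sample_id, names(groups))
  if (length(miss) > 0) {
    abort(sprintf("no group for sample(s): %s", paste(miss, collapse = ", ")))
  }
  fr$group <- unname(groups[fr$sample_id])
  out <- dplyr::summarise(
    dplyr::group_by(fr, .data$group),
    n_samples = dplyr::n(),
    min_fraction = min(.data$methane_cycler),
    max_fraction = max(.data$methane_cycler),
    .groups = "drop")
  if (any(out$n_samples == 0)) abort("empty group")
  out
}
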