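#' @importFrom rlang .data
#' @importFrom stats aov coef cor.test lm mahalanobis na.omit predict rbeta
#'   rbinom rlnorm rmultinom rnorm runif sd setNames t.test var TukeyHSD
#'   dbinom plogis qt
#' @importFrom utils head
NULL

TAXON_RANKS <- c("class", "order", "family", "genus", "species")
FISH_CLASSES <- c("bony", "cartilaginous")
SOURCE_CATEGORIES <- c("A", "B", "C")
TROPHIC_GROUPS <- c(
  "invertivore", "herbivore", "macrocarnivore",
  "omnivore", "piscivore", "planktivore"
)
LINEAGE_SEP <- ";"

required_columns <- list(
  taxa    = c("taxon_id", "name", "rank", "lineage", "fish_class"),
  sites   = c(
    "site_id", "name", "latitude", "source_category", "mesh_mm",
    "volume_m3", "median_age_cal_bp", "quantification_basis"
  ),
  counts  = c("site_id", "cultural_phase", "taxon_id", "count"),
  traits  = c(
    "species", "trophic_level", "trophic_group",
    "max_body_size_cm", "max_body_mass_g"
  ),
  periods = c("period_id", "species")
)

check_columns <- function(df, table) {
  missing <- setdiff(required_columns[[table]], names(df))
  if (length(missing) > 0L) {
    stop(
      sprintf(
        "schema error in '%s' table: missing column(s) %s",
        table, paste(sQuote(missing), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  invisible(df)
}

parse_numeric_column <- function(x, column, table) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0L) {
    stop(
      sprintf(
        "parse error in '%s' table: non-numeric %s at row(s) %s",
        table, column, paste(head(bad, 10L), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  out
}

#' Split a lineage string into its ordered taxon path
#'
#' Lineages are stored as a single `;`-separated string running from class
#' down to the record's own name (missing intermediate ranks simply absent),
#' e.g. `"Actinopterygii;Siluriformes;Ariidae;Genidens;Genidens barbus"`.
#'
#' @param lineage Character vector of lineage strings.
#' @return A list of character vectors, one path per input element.
#' @export
lineage_path <- function(lineage) {
  strsplit(as.character(lineage), LINEAGE_SEP, fixed = TRUE) |>
    lapply(trimws)
}

#' Assemble a validated fish-assemblage dataset
#'
#' Bundles the five tables the pipeline consumes (taxa, sites, counts,
#' traits, period catch lists) into a single object after checking the
#' column layout and referential integrity: every count row must join to a
#' known site and a known taxon.
#'
#' @param taxa Data frame with columns `taxon_id`, `name`, `rank`,
#'   `lineage`, `fish_class`.
#' @param sites Data frame with columns `site_id`, `name`, `latitude`
#'   (signed decimal degrees, southern hemisphere negative),
#'   `source_category` (A/B/C), `mesh_mm`, `volume_m3`,
#'   `median_age_cal_bp`, `quantification_basis` (NISP or MNI).
#' @param counts Data frame with columns `site_id`, `cultural_phase`,
#'   `taxon_id`, `count`.
#' @param traits Data frame with columns `species`, `trophic_level`,
#'   `trophic_group`, `max_body_size_cm`, `max_body_mass_g`.
#' @param periods Data frame with columns `period_id`, `species` (one row
#'   per species present in a period's catch).
#' @return A `catch_dataset` object (a named list of tibbles).
#' @seealso [read_dataset()], [validate_dataset()]
#' @export
catch_dataset <- function(taxa, sites, counts, traits, periods) {
  taxa <- tibble::as_tibble(taxa)
  sites <- tibble::as_tibble(sites)
  counts <- tibble::as_tibble(counts)
  traits <- tibble::as_tibble(traits)
  periods <- tibble::as_tibble(periods)

  check_columns(taxa, "taxa")
  check_columns(sites, "sites")
  check_columns(counts, "counts")
  check_columns(traits, "traits")
  check_columns(periods, "periods")

  counts$count <- parse_numeric_column(counts$count, "count", "counts")
  for (col in c("latitude", "mesh_mm", "volume_m3", "median_age_cal_bp")) {
    sites[[col]] <- parse_numeric_column(sites[[col]], col, "sites")
  }
  for (col in c("trophic_level", "max_body_size_cm", "max_body_mass_g")) {
    traits[[col]] <- parse_numeric_column(traits[[col]], col, "traits")
  }

  unknown_taxa <- setdiff(counts$taxon_id, taxa$taxon_id)
  if (length(unknown_taxa) > 0L) {
    stop(
      sprintf(
        "integrity error: count rows reference unknown taxon_id(s): %s",
        paste(sQuote(unknown_taxa), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  unknown_sites <- setdiff(counts$site_id, sites$site_id)
  if (length(unknown_sites) > 0L) {
    stop(
      sprintf(
        "integrity error: count rows reference unknown site_id(s): %s",
        paste(sQuote(unknown_sites), collapse = ", ")
      ),
      call. = FALSE
    )
  }

  structure(
    list(
      taxa = taxa, sites = sites, counts = counts,
      traits = traits, periods = periods
    ),
    class = "catch_dataset"
  )
}

#' @export
print.catch_dataset <- function(x, ...) {
  n_assemblages <- nrow(dplyr::distinct(
    x$counts, .data$site_id, .data$cultural_phase
  ))
  cat(
    "<catch_dataset>\n",
    sprintf("  taxa:        %d records\n", nrow(x$taxa)),
    sprintf("  sites:       %d\n", nrow(x$sites)),
    sprintf(
      "  counts:      %d rows in %d assemblages (total NISP/MNI %s)\n",
      nrow(x$counts), n_assemblages,
      format(sum(x$counts$count), big.mark = ",")
    ),
    sprintf("  traits:      %d species\n", nrow(x$traits)),
    sprintf(
      "  periods:     %d (%d presence rows)\n",
      length(unique(x$periods$period_id)), nrow(x$periods)
    ),
    sep = ""
  )
  invisible(x)
}

#' Read the five pipeline tables from CSV
#'
#' CSV dialect: UTF-8, comma separators, mandatory header, `.` decimal
#' mark, empty cells read as missing. A `present` column in the periods
#' table, when given, keeps only rows with a truthy value so wide
#' presence/absence exports can be stacked into the long layout.
#'
#' @param taxa_csv,sites_csv,counts_csv,traits_csv,periods_csv File paths.
#' @return A validated [catch_dataset()].
#' @export
read_dataset <- function(taxa_csv, sites_csv, counts_csv, traits_csv,
                         periods_csv) {
  for (f in c(taxa_csv, sites_csv, counts_csv, traits_csv, periods_csv)) {
    if (!file.exists(f)) {
      stop(sprintf("input file not found: %s", f), call. = FALSE)
    }
  }
  read <- function(path) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  periods <- read(periods_csv)
  if ("present" %in% names(periods)) {
    periods <- dplyr::filter(
      periods,
      .data$present %in% c(1, "1", TRUE, "TRUE", "true", "x", "yes")
    )
    periods$present <- NULL
  }
  catch_dataset(
    taxa = read(taxa_csv), sites = read(sites_csv),
    counts = read(counts_csv), traits = read(traits_csv),
    periods = periods
  )
}

#' Read a wide presence/absence period table
#'
#' Defensive loader for supplementary-style exports where each row is a
#' species and each remaining column is a time period scored 1/0 (or
#' x/blank) for presence. The first column whose name matches
#' `species_col` (default: the first column) supplies species names.
#'
#' @param path CSV file path.
#' @param species_col Name of the species column; `NULL` takes the first.
#' @return A long tibble with columns `period_id`, `species`.
#' @export
read_period_presence <- function(path, species_col = NULL) {
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(wide) < 2L) {
    stop("presence/absence table needs a species column plus >=1 period",
      call. = FALSE
    )
  }
  if (is.null(species_col)) species_col <- names(wide)[1L]
  if (!species_col %in% names(wide)) {
    stop(sprintf("species column %s not found", sQuote(species_col)),
      call. = FALSE
    )
  }
  wide <- dplyr::mutate(
    wide,
    dplyr::across(-dplyr::all_of(species_col), as.character)
  )
  long <- tidyr::pivot_longer(
    wide,
    cols = -dplyr::all_of(species_col),
    names_to = "period_id", values_to = "present"
  )
  present <- trimws(tolower(as.character(long$present)))
  keep <- !is.na(present) & present %in% c("1", "x", "yes", "true", "p")
  tibble::tibble(
    period_id = long$period_id[keep],
    species = trimws(long[[species_col]][keep])
  ) |> dplyr::distinct()
}

#' Write a dataset back to the five CSV files
#'
#' @param dataset A [catch_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the five file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "catch_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(dataset), function(tab) {
    p <- file.path(dir, paste0(tab, ".csv"))
    readr::write_csv(dataset[[tab]], p, na = "")
    p
  }, character(1))
  invisible(paths)
}

violation <- function(table, record_id, field, message) {
  tibble::tibble(
    table = table, record_id = as.character(record_id),
    field = field, message = message
  )
}

#' List invariant violations in a dataset
#'
#' Checks every domain invariant and returns the breaches as data rather
#' than raising: rank/lineage consistency, fish-class vocabulary, trophic
#' levels inside \[2.0, 4.9\], strictly positive sizes, masses and sediment
#' volumes, non-negative counts with at least one positive count per
#' assemblage, qualitative (source C) sites carrying at most presence
#' markers (count = 1, keeping them usable for richness and occurrence but
#' never abundance), and period
#' species resolving in the trait table. An empty result means the dataset
#' is clean; the check is idempotent and row-order independent.
#'
#' @param dataset A [catch_dataset()].
#' @return A tibble with columns `table`, `record_id`, `field`, `message`;
#'   zero rows when every invariant holds.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "catch_dataset"))
  v <- list()
  tx <- dataset$taxa

  bad_rank <- !tx$rank %in% TAXON_RANKS
  if (any(bad_rank)) {
    v[[length(v) + 1L]] <- violation(
      "taxa", tx$taxon_id[bad_rank], "rank",
      sprintf("rank %s not one of %s", sQuote(tx$rank[bad_rank]),
        paste(TAXON_RANKS, collapse = "/"))
    )
  }
  bad_class <- !tx$fish_class %in% FISH_CLASSES
  if (any(bad_class)) {
    v[[length(v) + 1L]] <- violation(
      "taxa", tx$taxon_id[bad_class], "fish_class",
      "fish_class must be 'bony' or 'cartilaginous'"
    )
  }
  paths <- lineage_path(tx$lineage)
  depth <- lengths(paths)
  rank_pos <- match(tx$rank, TAXON_RANKS)
  bad_depth <- !bad_rank & !is.na(rank_pos) & depth > rank_pos
  if (any(bad_depth)) {
    v[[length(v) + 1L]] <- violation(
      "taxa", tx$taxon_id[bad_depth], "lineage",
      sprintf("lineage depth %d exceeds what rank '%s' allows",
        depth[bad_depth], tx$rank[bad_depth])
    )
  }

  st <- dataset$sites
  bad_src <- !st$source_category %in% SOURCE_CATEGORIES
  if (any(bad_src)) {
    v[[length(v) + 1L]] <- violation(
      "sites", st$site_id[bad_src], "source_category",
      "source_category must be A, B or C"
    )
  }
  bad_vol <- !is.na(st$volume_m3) & st$volume_m3 <= 0
  if (any(bad_vol)) {
    v[[length(v) + 1L]] <- violation(
      "sites", st$site_id[bad_vol], "volume_m3",
      "volume_m3 must be > 0 when present"
    )
  }
  bad_mesh <- !is.na(st$mesh_mm) & st$mesh_mm <= 0
  if (any(bad_mesh)) {
    v[[length(v) + 1L]] <- violation(
      "sites", st$site_id[bad_mesh], "mesh_mm",
      "mesh_mm must be > 0 when present"
    )
  }
  bad_age <- !is.na(st$median_age_cal_bp) & st$median_age_cal_bp < 0
  if (any(bad_age)) {
    v[[length(v) + 1L]] <- violation(
      "sites", st$site_id[bad_age], "median_age_cal_bp",
      "median_age_cal_bp must be >= 0"
    )
  }
  bad_basis <- !st$quantification_basis %in% c("NISP", "MNI")
  if (any(bad_basis)) {
    v[[length(v) + 1L]] <- violation(
      "sites", st$site_id[bad_basis], "quantification_basis",
      "quantification_basis must be NISP or MNI"
    )
  }
  # qualitative (source C) sites contribute taxon lists to richness and
  # occurrence but no quantitative abundance: presence markers (count = 1)
  # are allowed, anything larger is a violation
  c_sites <- st$site_id[st$source_category == "C"]
  c_rows <- dataset$counts[dataset$counts$site_id %in% c_sites, ]
  quant_c <- unique(c_rows$site_id[!is.na(c_rows$count) & c_rows$count > 1])
  if (length(quant_c) > 0L) {
    v[[length(v) + 1L]] <- violation(
      "sites", quant_c, "source_category",
      "qualitative (source C) sites may carry presence markers only"
    )
  }

  ct <- dataset$counts
  bad_count <- is.na(ct$count) | ct$count < 0
  if (any(bad_count)) {
    v[[length(v) + 1L]] <- violation(
      "counts",
      paste(ct$site_id[bad_count], ct$taxon_id[bad_count], sep = "/"),
      "count", "count must be a non-negative number"
    )
  }
  by_asm <- dplyr::summarise(
    dplyr::group_by(ct, .data$site_id, .data$cultural_phase),
    total = sum(.data$count, na.rm = TRUE), .groups = "drop"
  )
  empty <- by_asm$total <= 0
  if (any(empty)) {
    v[[length(v) + 1L]] <- violation(
      "counts",
      paste(by_asm$site_id[empty], by_asm$cultural_phase[empty], sep = "/"),
      "count", "assemblage has no positive count"
    )
  }

  tr <- dataset$traits
  bad_tl <- is.na(tr$trophic_level) |
    tr$trophic_level < 2.0 | tr$trophic_level > 4.9
  if (any(bad_tl)) {
    v[[length(v) + 1L]] <- violation(
      "traits", tr$species[bad_tl], "trophic_level",
      "trophic_level must lie in [2.0, 4.9]"
    )
  }
  bad_tg <- !tr$trophic_group %in% TROPHIC_GROUPS
  if (any(bad_tg)) {
    v[[length(v) + 1L]] <- violation(
      "traits", tr$species[bad_tg], "trophic_group",
      sprintf("trophic_group must be one of %s",
        paste(TROPHIC_GROUPS, collapse = "/"))
    )
  }
  for (col in c("max_body_size_cm", "max_body_mass_g")) {
    bad <- is.na(tr[[col]]) | tr[[col]] <= 0
    if (any(bad)) {
      v[[length(v) + 1L]] <- violation(
        "traits", tr$species[bad], col,
        sprintf("%s must be strictly positive", col)
      )
    }
  }

  orphan <- setdiff(dataset$periods$species, tr$species)
  if (length(orphan) > 0L) {
    v[[length(v) + 1L]] <- violation(
      "periods", orphan, "species",
      "period species missing from the trait table"
    )
  }

  if (length(v) == 0L) {
    return(violation(character(), character(), character(), character()))
  }
  dplyr::bind_rows(v)
}
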