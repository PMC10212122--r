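# Assemblage-level metrics: aggregation, relative abundance with
# class-level exclusion, occurrence frequency, richness under the Minimal
# Level of Taxonomic Identification, densities, trophic-level attribution,
# weighted average trophic level and linear trend fits.

#' Aggregate count records sharing a site and cultural phase
#'
#' Sums per-taxon counts over records that describe the same occupation
#' (e.g. distinct excavation areas published separately). Total NISP is
#' preserved exactly.
#'
#' @param records Count rows (`site_id`, `cultural_phase`, `taxon_id`,
#'   `count`) all belonging to one site and phase.
#' @param sites Optional site table used to reject mixtures of NISP- and
#'   MNI-quantified records.
#' @return A count tibble with one row per taxon.
#' @export
aggregate_counts <- function(records, sites = NULL) {
  records <- tibble::as_tibble(records)
  key <- dplyr::distinct(records, .data$site_id, .data$cultural_phase)
  if (nrow(key) != 1L) {
    stop("records span more than one site/cultural phase; aggregate refused",
      call. = FALSE
    )
  }
  if (!is.null(sites)) {
    basis <- unique(
      sites$quantification_basis[sites$site_id %in% records$site_id]
    )
    if (length(basis) > 1L) {
      stop("mixed quantification bases (NISP and MNI) within one assemblage",
        call. = FALSE
      )
    }
  }
  dplyr::summarise(
    dplyr::group_by(
      records, .data$site_id, .data$cultural_phase, .data$taxon_id
    ),
    count = sum(.data$count), .groups = "drop"
  )
}

#' Relative taxonomic abundance with class-level exclusion
#'
#' Computes each taxon's share of the identified remains: specimens
#' recorded only at class level (Actinopterygii, Elasmobranchii) stay in
#' the totals and in the per-class identified fractions but are removed
#' from the denominator of the percentages, which therefore sum to 100
#' over the identified taxa. Percentages are kept at full precision in
#' `rel_abundance`; `rel_abundance_display` rounds to one decimal.
#'
#' @param assemblage Count rows for one assemblage.
#' @param taxa Taxon table resolving `taxon_id` to rank and fish class.
#' @return A list of class `abundance_summary`: `per_taxon` tibble,
#'   `identified_fraction` per fish class, `total_nisp`,
#'   `identified_nisp`.
#' @export
relative_abundance <- function(assemblage, taxa) {
  assemblage <- tibble::as_tibble(assemblage)
  stopifnot(nrow(assemblage) > 0)
  joined <- dplyr::left_join(
    assemblage, taxa[, c("taxon_id", "name", "rank", "fish_class")],
    by = "taxon_id"
  )
  is_class <- joined$rank == "class"
  total <- sum(joined$count)
  identified <- sum(joined$count[!is_class])

  id_frac <- vapply(FISH_CLASSES, function(fc) {
    tot_fc <- sum(joined$count[joined$fish_class == fc])
    if (tot_fc == 0) {
      return(NA_real_)
    }
    sum(joined$count[joined$fish_class == fc & !is_class]) / tot_fc
  }, numeric(1))

  if (identified == 0) {
    warning("all remains identified at class level only; ",
      "no relative abundances computed",
      call. = FALSE
    )
    per_taxon <- tibble::tibble(
      taxon_id = character(), name = character(), rank = character(),
      fish_class = character(), nisp = numeric(),
      rel_abundance = numeric(), rel_abundance_display = numeric()
    )
  } else {
    kept <- joined[!is_class & joined$count > 0, ]
    per_taxon <- tibble::tibble(
      taxon_id = kept$taxon_id, name = kept$name, rank = kept$rank,
      fish_class = kept$fish_class, nisp = kept$count,
      rel_abundance = 100 * kept$count / identified
    )
    per_taxon$rel_abundance_display <- round(per_taxon$rel_abundance, 1)
    per_taxon <- dplyr::arrange(per_taxon, dplyr::desc(.data$nisp))
  }

  structure(
    list(
      per_taxon = per_taxon,
      identified_fraction = id_frac,
      total_nisp = total,
      identified_nisp = identified
    ),
    class = "abundance_summary"
  )
}

#' @export
print.abundance_summary <- function(x, ...) {
  cat(sprintf(
    "<abundance_summary> total NISP %s, identified %s (%.1f%%)\n",
    format(x$total_nisp, big.mark = ","),
    format(x$identified_nisp, big.mark = ","),
    ifelse(x$total_nisp > 0, 100 * x$identified_nisp / x$total_nisp, NA)
  ))
  print(head(x$per_taxon, 10))
  invisible(x)
}

descendant_ids <- function(taxon_name, taxa) {
  paths <- lineage_path(taxa$lineage)
  hit <- vapply(
    paths, function(p) taxon_name %in% p, logical(1)
  )
  taxa$taxon_id[hit]
}

#' Occurrence frequency of a taxon across sites
#'
#' A taxon "occurs" at a site when the taxon itself or any descendant
#' (e.g. a member species for a family-level query) has a positive count
#' there, so family-level frequencies can exceed any single member's. The
#' site universe defaults to every site in the dataset, i.e. all sites
#' with fish remains regardless of source category.
#'
#' @param dataset A [catch_dataset()].
#' @param taxon_name Name of the queried taxon (any rank).
#' @param site_universe Character vector of site ids; default all sites.
#' @return A list: `percent` (full precision), `percent_display` (rounded
#'   to the nearest integer), `n_occupied`, `n_universe`.
#' @export
occurrence_frequency <- function(dataset, taxon_name, site_universe = NULL) {
  if (is.null(site_universe)) site_universe <- dataset$sites$site_id
  if (length(site_universe) == 0L) {
    stop("empty site universe", call. = FALSE)
  }
  ids <- descendant_ids(taxon_name, dataset$taxa)
  occ <- dataset$counts$site_id[
    dataset$counts$taxon_id %in% ids & dataset$counts$count > 0
  ]
  n_occ <- length(intersect(unique(occ), site_universe))
  pct <- 100 * n_occ / length(site_universe)
  list(
    percent = pct, percent_display = round(pct),
    n_occupied = n_occ, n_universe = length(site_universe)
  )
}

#' Species richness under the Minimal Level of Taxonomic Identification
#'
#' Counts the distinct taxa of an assemblage after collapsing nested
#' records: a taxon is discarded when it is an ancestor of another taxon
#' present in the same assemblage (e.g. `Genidens sp.` alongside
#' `Genidens barbus` contributes nothing), and class-level records never
#' count. Equivalently, the richness is the number of leaves of the
#' presence forest induced by the assemblage's lineages.
#'
#' @param assemblage Count rows for one assemblage.
#' @param taxa Taxon table with lineages.
#' @return Integer richness.
#' @export
species_richness_mlti <- function(assemblage, taxa) {
  present <- unique(assemblage$taxon_id[assemblage$count > 0])
  tx <- taxa[match(present, taxa$taxon_id), ]
  tx <- tx[tx$rank != "class", ]
  if (nrow(tx) == 0L) {
    return(0L)
  }
  paths <- lineage_path(tx$lineage)
  ancestors <- unique(unlist(lapply(paths, function(p) p[-length(p)])))
  is_leaf <- !tx$name %in% ancestors
  sum(is_leaf)
}

#' Specimen density per excavated volume
#'
#' @param assemblage Count rows for one assemblage.
#' @param site The matching site row (needs `volume_m3`).
#' @return NISP per cubic metre, or `NA` (with a message) when the volume
#'   is unreported, signalling exclusion from density analyses.
#' @export
nisp_density <- function(assemblage, site) {
  vol <- site$volume_m3[1]
  if (is.na(vol)) {
    message(sprintf(
      "site %s lacks an excavated volume; excluded from density analyses",
      site$site_id[1]
    ))
    return(NA_real_)
  }
  stopifnot(vol > 0)
  sum(assemblage$count) / vol
}

#' Richness normalised by total specimen count
#'
#' @param assemblage Count rows for one assemblage.
#' @param taxa Taxon table with lineages.
#' @return SR/NISP, the MLTI richness divided by the total count.
#' @export
sr_per_nisp <- function(assemblage, taxa) {
  total <- sum(assemblage$count)
  stopifnot(total > 0)
  species_richness_mlti(assemblage, taxa) / total
}

#' Attribute a trophic level to a taxon of any sub-class rank
#'
#' Species take their trophic level straight from the trait table. Genus,
#' family and order records take the arithmetic mean of the trophic levels
#' of regional species falling inside the taxon — by default the species
#' recorded in the archaeological dataset — or, when none are recorded, of
#' a configured fallback species list (e.g. a regional biodiversity
#' checklist). The provenance of the value is attached.
#'
#' @param taxon_name Queried taxon name (rank below class).
#' @param taxa Taxon table with lineages.
#' @param traits Trait table.
#' @param regional_species Species considered "recorded in the region";
#'   defaults to every species in the trait table.
#' @param fallback_species Optional checklist used when no regional
#'   species falls inside the taxon.
#' @return The trophic level (numeric), with attributes `source` (one of
#'   `"species"`, `"regional_mean"`, `"fallback_mean"`) and
#'   `species_used`; `NA` with a warning when nothing resolves.
#' @export
taxon_trophic_level <- function(taxon_name, taxa, traits,
                                regional_species = NULL,
                                fallback_species = NULL) {
  if (is.null(regional_species)) regional_species <- traits$species
  rank <- taxa$rank[match(taxon_name, taxa$name)]
  if (!is.na(rank) && rank == "class") {
    stop("trophic levels are not attributed at class level", call. = FALSE)
  }
  direct <- traits$trophic_level[match(taxon_name, traits$species)]
  if (!is.na(rank) && rank == "species" || !is.na(direct)) {
    if (is.na(direct)) {
      warning(sprintf("no trait record for species %s", taxon_name),
        call. = FALSE
      )
      return(structure(NA_real_, source = "unresolved"))
    }
    return(structure(direct, source = "species", species_used = taxon_name))
  }

  member_ids <- descendant_ids(taxon_name, taxa)
  members <- taxa$name[taxa$taxon_id %in% member_ids &
    taxa$rank == "species"]
  pick <- function(pool, label) {
    used <- intersect(intersect(members, pool), traits$species)
    if (length(used) == 0L) {
      return(NULL)
    }
    structure(
      mean(traits$trophic_level[match(used, traits$species)]),
      source = label, species_used = used
    )
  }
  out <- pick(regional_species, "regional_mean")
  if (is.null(out) && !is.null(fallback_species)) {
    out <- pick(fallback_species, "fallback_mean")
  }
  if (is.null(out)) {
    warning(sprintf(
      "no trophic level resolvable for %s; excluded from WATL", taxon_name
    ), call. = FALSE)
    out <- structure(NA_real_, source = "unresolved")
  }
  out
}

#' Weighted average trophic level of an assemblage
#'
#' `sum(w_i * TL_i)` with weights `w_i` given by the class-level-excluded
#' relative abundances, renormalised over the taxa whose trophic level
#' resolves; with `weighting = "presence"` every resolvable taxon weighs
#' equally. Invariant to rescaling all counts by a positive constant and
#' always bounded by the minimum and maximum contributing trophic level.
#'
#' @param assemblage Count rows for one assemblage.
#' @param taxa Taxon table.
#' @param traits Trait table.
#' @param regional_species,fallback_species Passed to
#'   [taxon_trophic_level()].
#' @param weighting `"nisp"` (abundance-weighted, default) or
#'   `"presence"`.
#' @return The weighted average trophic level (numeric scalar).
#' @export
watl <- function(assemblage, taxa, traits, regional_species = NULL,
                 fallback_species = NULL,
                 weighting = c("nisp", "presence")) {
  weighting <- match.arg(weighting)
  summ <- relative_abundance(assemblage, taxa)
  pt <- summ$per_taxon
  if (nrow(pt) == 0L) {
    return(NA_real_)
  }
  tls <- vapply(pt$name, function(nm) {
    suppressWarnings(as.numeric(taxon_trophic_level(
      nm, taxa, traits, regional_species, fallback_species
    )))
  }, numeric(1))
  ok <- !is.na(tls)
  if (!any(ok)) {
    warning("no taxon with a resolvable trophic level", call. = FALSE)
    return(NA_real_)
  }
  w <- if (weighting == "nisp") pt$rel_abundance[ok] else rep(1, sum(ok))
  sum(w * tls[ok]) / sum(w)
}

#' Ordinary least-squares trend with a 95% confidence band
#'
#' Fits `y ~ x` and reports slope, intercept, Pearson r, the slope's
#' two-sided p-value and a pointwise 95% confidence band, as used for
#' latitudinal and chronological trends in richness, trophic level and
#' cartilaginous-fish share.
#'
#' @param x,y Numeric vectors (>= 3 finite pairs; `x` must vary).
#' @param band_n Number of evaluation points for the confidence band.
#' @return A list of class `trend_fit`: `slope`, `intercept`, `r`, `p`,
#'   `n`, `band` (tibble `x`, `fit`, `lwr`, `upr`), and the `model`.
#' @export
trend_fit <- function(x, y, band_n = 100L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (sd(x) == 0) stop("x is constant; no trend estimable", call. = FALSE)
  fit <- lm(y ~ x)
  # summary.lm warns on exact fits (r = 1); those are legitimate here
  sm <- suppressWarnings(summary(fit))
  grid <- tibble::tibble(x = seq(min(x), max(x), length.out = band_n))
  ci <- predict(fit, newdata = grid, interval = "confidence", level = 0.95)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r = unname(sign(coef(fit)[2]) * sqrt(sm$r.squared)),
      p = unname(sm$coefficients[2, 4]),
      n = length(x),
      band = tibble::tibble(
        x = grid$x, fit = ci[, "fit"], lwr = ci[, "lwr"], upr = ci[, "upr"]
      ),
      model = fit
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> slope %.4g, r = %.2f, p = %.4f, n = %d\n",
    x$slope, x$r, x$p, x$n
  ))
  invisible(x)
}

#' Survey-level summary of the compiled record
#'
#' Reproduces the data-assessment percentages for a compiled survey:
#' source-category shares, share of sites with quantitative abundance
#' data (sources A and B), share of those with a reported excavated
#' volume, and the sieving mesh-size breakdown.
#'
#' @param sites Site table.
#' @return A list of tibbles/values: `n_sites`, `source_shares`,
#'   `quantified_share_pct`, `volume_reported_share_pct`, `mesh_shares`.
#' @export
survey_summary <- function(sites) {
  n <- nrow(sites)
  src <- dplyr::count(sites, .data$source_category)
  src$share_pct <- 100 * src$n / n

  quantified <- sites[sites$source_category %in% c("A", "B"), ]
  nq <- nrow(quantified)
  with_vol <- sum(!is.na(quantified$volume_m3))

  sieved <- quantified[!is.na(quantified$mesh_mm), ]
  mesh <- dplyr::count(sieved, .data$mesh_mm)
  mesh$share_pct <- if (nrow(sieved) > 0) 100 * mesh$n / nrow(sieved) else
    numeric(0)

  list(
    n_sites = n,
    source_shares = src,
    quantified_n = nq,
    quantified_share_pct = 100 * nq / n,
    volume_reported_share_pct = if (nq > 0) 100 * with_vol / nq else NA_real_,
    sieved_n = nrow(sieved),
    mesh_shares = mesh
  )
}
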