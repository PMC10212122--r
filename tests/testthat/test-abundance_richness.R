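test_that("aggregation sums per-taxon counts and preserves the total", {
  a <- tibble::tibble(
    site_id = "S1", cultural_phase = "Sambaqui",
    taxon_id = c("A", "B"), count = c(10, 5)
  )
  b <- tibble::tibble(
    site_id = "S1", cultural_phase = "Sambaqui",
    taxon_id = "A", count = 2
  )
  agg <- aggregate_counts(rbind(a, b))
  expect_equal(
    setNames(agg$count, agg$taxon_id)[c("A", "B")],
    c(A = 12, B = 5)
  )

  # identity on a single record set
  expect_equal(
    aggregate_counts(a)[order(aggregate_counts(a)$taxon_id), ]$count,
    a[order(a$taxon_id), ]$count
  )

  # refuses to mix assemblages
  expect_error(
    aggregate_counts(rbind(
      a, tibble::tibble(
        site_id = "S2", cultural_phase = "Sambaqui",
        taxon_id = "A", count = 1
      )
    )),
    "more than one site"
  )
})

test_that("randomly partitioned assemblages re-aggregate to the original", {
  sim <- simulate_dataset(small_sim_config(seed = 21L))
  counts <- sim$dataset$counts
  asm <- counts[counts$site_id == counts$site_id[1] &
    counts$cultural_phase == counts$cultural_phase[1], ]
  set.seed(99)
  for (k in c(2L, 5L)) {
    parts <- lapply(seq_len(nrow(asm)), function(i) {
      split_counts <- rmultinom(1, asm$count[i], rep(1 / k, k))[, 1]
      tibble::tibble(
        site_id = asm$site_id[i], cultural_phase = asm$cultural_phase[i],
        taxon_id = asm$taxon_id[i], count = split_counts
      )
    })
    rejoined <- aggregate_counts(dplyr::bind_rows(parts))
    merged <- merge(rejoined, asm, by = "taxon_id")
    expect_equal(merged$count.x, merged$count.y)
  }
})

test_that("relative abundance excludes class-level remains from shares", {
  ds <- tiny_dataset()

  # printed class totals treated as a two-taxon summary
  two <- tibble::tibble(
    site_id = "S1", cultural_phase = "Sambaqui",
    taxon_id = c("species:Genidens barbus", "species:Carcharias taurus"),
    count = c(876622, 10603)
  )
  summ <- relative_abundance(two, ds$taxa)
  expect_equal(sort(summ$per_taxon$rel_abundance_display), c(1.2, 98.8))

  # class exclusion halves the denominator
  mixed <- tibble::tibble(
    site_id = "S1", cultural_phase = "Sambaqui",
    taxon_id = c(
      "class:Actinopterygii", "species:Genidens barbus",
      "species:Micropogonias furnieri"
    ),
    count = c(50, 25, 25)
  )
  s2 <- relative_abundance(mixed, ds$taxa)
  expect_equal(s2$per_taxon$rel_abundance, c(50, 50))
  expect_equal(s2$total_nisp, 100)
  expect_equal(s2$identified_nisp, 50)
  expect_equal(unname(s2$identified_fraction["bony"]), 0.5)

  # shares always sum to 100 over included taxa
  expect_equal(sum(s2$per_taxon$rel_abundance), 100, tolerance = 1e-9)
})

test_that("relative abundance matches a brute-force recomputation", {
  sim <- simulate_dataset(small_sim_config(seed = 22L))
  ds <- sim$dataset
  asm <- ds$counts[ds$counts$site_id == ds$counts$site_id[1] &
    ds$counts$cultural_phase == ds$counts$cultural_phase[1], ]
  summ <- relative_abundance(asm, ds$taxa)

  # oracle from raw joins, no package arithmetic
  rank_of <- setNames(ds$taxa$rank, ds$taxa$taxon_id)
  keep <- rank_of[asm$taxon_id] != "class"
  denom <- sum(asm$count[keep])
  want <- 100 * asm$count[keep] / denom
  names(want) <- asm$taxon_id[keep]
  got <- setNames(summ$per_taxon$rel_abundance, summ$per_taxon$taxon_id)
  expect_equal(got[names(want)], want, tolerance = 1e-12)
  expect_equal(sum(summ$per_taxon$rel_abundance), 100, tolerance = 1e-9)
})

test_that("aggregation commutes with the abundance summary", {
  sim <- simulate_dataset(small_sim_config(seed = 23L))
  ds <- sim$dataset
  asm <- ds$counts[ds$counts$site_id == ds$counts$site_id[2] &
    ds$counts$cultural_phase == ds$counts$cultural_phase[2], ]
  set.seed(7)
  parts <- dplyr::bind_rows(lapply(seq_len(nrow(asm)), function(i) {
    s <- rmultinom(1, asm$count[i], c(0.4, 0.6))[, 1]
    tibble::tibble(
      site_id = asm$site_id[i], cultural_phase = asm$cultural_phase[i],
      taxon_id = asm$taxon_id[i], count = s
    )
  }))
  s_agg <- relative_abundance(aggregate_counts(parts), ds$taxa)
  s_orig <- relative_abundance(asm, ds$taxa)
  a <- setNames(s_agg$per_taxon$rel_abundance, s_agg$per_taxon$taxon_id)
  b <- setNames(s_orig$per_taxon$rel_abundance, s_orig$per_taxon$taxon_id)
  expect_equal(a[sort(names(a))], b[sort(names(b))], tolerance = 1e-12)
})

test_that("occurrence frequency counts descendants hierarchically", {
  # 53-site universe (44 quantified A/B + 9 qualitative C), Genidens
  # barbus in 37, any Ariidae member in 49, elasmobranchs in 28; the C
  # sites enter via presence markers (count = 1)
  n_sites <- 53L
  sites <- tibble::tibble(
    site_id = sprintf("st%02d", 1:n_sites),
    name = sprintf("st%02d", 1:n_sites),
    latitude = -26,
    source_category = c(rep("A", 40), rep("B", 4), rep("C", 9)),
    mesh_mm = NA_real_, volume_m3 = NA_real_,
    median_age_cal_bp = NA_real_,
    quantification_basis = "NISP"
  )
  taxa <- tiny_taxa()
  mk <- function(site_ids, taxon_id, count = 1) {
    tibble::tibble(
      site_id = site_ids, cultural_phase = "Sambaqui",
      taxon_id = taxon_id, count = count
    )
  }
  counts <- dplyr::bind_rows(
    mk(sites$site_id[1:37], "species:Genidens barbus"),
    mk(sites$site_id[38:44], "species:Bagre bagre"), # Ariidae reaches 44
    mk(sites$site_id[45:49], "family:Ariidae"), # ... and 49 via C sites
    mk(sites$site_id[1:20], "genus:Sphyrna"),
    mk(sites$site_id[21:28], "species:Carcharias taurus")
  )
  ds <- catch_dataset(taxa, sites, counts, tiny_traits(), tiny_periods())
  expect_equal(nrow(validate_dataset(ds)), 0L)

  gb <- occurrence_frequency(ds, "Genidens barbus")
  expect_equal(gb$n_occupied, 37L)
  expect_equal(gb$n_universe, 53L)
  expect_equal(gb$percent_display, 70)

  ar <- occurrence_frequency(ds, "Ariidae")
  expect_equal(ar$n_occupied, 49L)
  expect_equal(ar$percent_display, 92)

  el <- occurrence_frequency(ds, "Elasmobranchii")
  expect_equal(el$n_occupied, 28L)
  expect_equal(el$percent_display, 53)

  # absent taxon scores zero; empty universe errors
  expect_equal(
    occurrence_frequency(ds, "Sciaenidae")$percent, 0
  )
  expect_error(
    occurrence_frequency(ds, "Ariidae", site_universe = character(0)),
    "empty"
  )
})

test_that("MLTI richness collapses nested records and drops classes", {
  taxa <- tiny_taxa()
  mk <- function(ids) {
    tibble::tibble(
      site_id = "S1", cultural_phase = "Sambaqui",
      taxon_id = ids, count = 1
    )
  }
  # nested lineage collapses to its deepest record
  expect_equal(species_richness_mlti(mk(c(
    "family:Ariidae", "genus:Genidens", "species:Genidens barbus"
  )), taxa), 1L)
  # sibling branches both count
  expect_equal(species_richness_mlti(mk(c(
    "genus:Genidens", "species:Bagre bagre"
  )), taxa), 2L)
  # class-level records never count
  expect_equal(species_richness_mlti(mk(c(
    "class:Actinopterygii", "class:Elasmobranchii"
  )), taxa), 0L)
  # adding an ancestor of a present taxon never changes SR
  base <- mk(c("species:Genidens barbus", "species:Carcharias taurus"))
  expect_equal(
    species_richness_mlti(rbind(base, mk("family:Ariidae")), taxa),
    species_richness_mlti(base, taxa)
  )
  # adding a fresh leaf increases SR by exactly 1
  expect_equal(
    species_richness_mlti(
      rbind(base, mk("species:Micropogonias furnieri")), taxa
    ),
    species_richness_mlti(base, taxa) + 1L
  )
})

test_that("MLTI richness equals the lineage-prefix leaf oracle", {
  sim <- simulate_dataset(small_sim_config(seed = 24L))
  taxa <- sim$dataset$taxa
  non_class <- taxa[taxa$rank != "class", ]
  set.seed(25)
  for (i in 1:150) {
    ids <- c(
      sample(non_class$taxon_id, sample(1:25, 1)),
      sample(taxa$taxon_id[taxa$rank == "class"], sample(0:2, 1))
    )
    asm <- tibble::tibble(
      site_id = "S", cultural_phase = "P", taxon_id = unique(ids), count = 1
    )
    got <- species_richness_mlti(asm, taxa)

    # oracle: count present sub-class lineages that are not a proper
    # prefix of another present lineage (string forest leaves)
    lin <- taxa$lineage[match(unique(ids), taxa$taxon_id)]
    rnk <- taxa$rank[match(unique(ids), taxa$taxon_id)]
    lin <- lin[rnk != "class"]
    is_prefix <- function(a, b) {
      a != b && startsWith(b, paste0(a, ";"))
    }
    leaves <- sum(vapply(lin, function(a) {
      !any(vapply(lin, function(b) is_prefix(a, b), logical(1)))
    }, logical(1)))
    expect_equal(got, leaves)
  }
})

test_that("densities and normalised richness are plain ratios", {
  ds <- tiny_dataset()
  asm <- tibble::tibble(
    site_id = "S1", cultural_phase = "Sambaqui",
    taxon_id = "species:Genidens barbus", count = 1000
  )
  expect_equal(nisp_density(asm, ds$sites[1, ]), 500)
  expect_message(
    d <- nisp_density(asm, ds$sites[3, ]),
    "excluded"
  )
  expect_true(is.na(d))

  ten_sp <- tibble::tibble(
    site_id = "S1", cultural_phase = "Sambaqui",
    taxon_id = c(
      "species:Genidens barbus", "species:Bagre bagre",
      "species:Micropogonias furnieri", "species:Carcharias taurus"
    ),
    count = c(400, 300, 200, 100)
  )
  expect_equal(sr_per_nisp(ten_sp, ds$taxa), 4 / 1000)
})

test_that("trophic-level attribution walks the taxonomy", {
  ds <- tiny_dataset()
  # species: identity
  tl <- taxon_trophic_level("Genidens barbus", ds$taxa, ds$traits)
  expect_equal(as.numeric(tl), 3.6)
  expect_equal(attr(tl, "source"), "species")

  # genus/family: mean over regional member species
  tl_fam <- taxon_trophic_level("Ariidae", ds$taxa, ds$traits)
  expect_equal(as.numeric(tl_fam), mean(c(3.6, 3.9)))
  expect_equal(attr(tl_fam, "source"), "regional_mean")

  # restricted regional list, then checklist fallback
  tl_gen <- taxon_trophic_level(
    "Ariidae", ds$taxa, ds$traits,
    regional_species = "Bagre bagre"
  )
  expect_equal(as.numeric(tl_gen), 3.9)
  tl_fb <- taxon_trophic_level(
    "Ariidae", ds$taxa, ds$traits,
    regional_species = "Carcharias taurus",
    fallback_species = c("Genidens barbus")
  )
  expect_equal(as.numeric(tl_fb), 3.6)
  expect_equal(attr(tl_fb, "source"), "fallback_mean")

  # nothing resolvable: NA with a warning; class level refused
  expect_warning(
    tl_na <- taxon_trophic_level(
      "Sciaenidae", ds$taxa, ds$traits,
      regional_species = "Carcharias taurus"
    ),
    "excluded"
  )
  expect_true(is.na(tl_na))
  expect_error(
    taxon_trophic_level("Actinopterygii", ds$taxa, ds$traits),
    "class"
  )
})

test_that("WATL is an abundance-weighted mean with stable invariants", {
  ds <- tiny_dataset()
  one <- tibble::tibble(
    site_id = "S1", cultural_phase = "Sambaqui",
    taxon_id = "species:Carcharias taurus", count = 7
  )
  expect_equal(watl(one, ds$taxa, ds$traits), 4.4)

  two <- tibble::tibble(
    site_id = "S1", cultural_phase = "Sambaqui",
    taxon_id = c("species:Genidens barbus", "species:Bagre bagre"),
    count = c(5, 5)
  )
  expect_equal(watl(two, ds$taxa, ds$traits), mean(c(3.6, 3.9)))

  # dot-product oracle on a synthetic assemblage, class counts present
  asm <- tibble::tibble(
    site_id = "S1", cultural_phase = "Sambaqui",
    taxon_id = c(
      "class:Actinopterygii", "species:Genidens barbus",
      "species:Bagre bagre", "species:Micropogonias furnieri"
    ),
    count = c(120, 30, 20, 50)
  )
  w <- c(30, 20, 50) / 100
  want <- sum(w * c(3.6, 3.9, 3.4))
  expect_equal(watl(asm, ds$taxa, ds$traits), want, tolerance = 1e-12)

  # invariant to rescaling all counts
  asm2 <- asm
  asm2$count <- asm2$count * 17
  expect_equal(
    watl(asm2, ds$taxa, ds$traits), watl(asm, ds$taxa, ds$traits),
    tolerance = 1e-12
  )

  # presence weighting ignores the counts
  expect_equal(
    watl(asm, ds$taxa, ds$traits, weighting = "presence"),
    mean(c(3.6, 3.9, 3.4)),
    tolerance = 1e-12
  )

  # bounded by the contributing trophic levels
  v <- watl(asm, ds$taxa, ds$traits)
  expect_gte(v, 3.4)
  expect_lte(v, 3.9)
})

test_that("trend fits recover exact lines and ignore row order", {
  x <- c(1, 2, 3, 4, 5)
  fit <- trend_fit(x, 2 * x)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-9)

  set.seed(31)
  xr <- rnorm(30)
  yr <- 1.5 * xr + rnorm(30)
  perm <- sample(30)
  f1 <- trend_fit(xr, yr)
  f2 <- trend_fit(xr[perm], yr[perm])
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f1$p, f2$p, tolerance = 1e-12)

  expect_error(trend_fit(rep(1, 5), rnorm(5)), "constant")
  expect_error(trend_fit(1:2, 1:2), "3 points")
})

test_that("the 95% confidence band covers a known slope ~95% of the time", {
  set.seed(32)
  covered <- replicate(400, {
    x <- runif(25, 0, 10)
    y <- 1 + 0.8 * x + rnorm(25, 0, 1.5)
    fit <- trend_fit(x, y)
    ci <- confint(fit$model)["x", ]
    ci[1] <= 0.8 && 0.8 <= ci[2]
  })
  expect_gt(mean(covered), 0.91)
  expect_lt(mean(covered), 0.99)
})

test_that("survey summaries reproduce share arithmetic", {
  sites <- tibble::tibble(
    site_id = sprintf("s%02d", 1:53),
    name = sprintf("s%02d", 1:53),
    latitude = -27,
    source_category = c(rep("A", 35), rep("B", 9), rep("C", 9)),
    mesh_mm = c(
      rep(2, 10), rep(3, 10), rep(4, 3), rep(5, 9), rep(NA, 21)
    ),
    volume_m3 = c(rep(1, 37), rep(NA, 16)),
    median_age_cal_bp = NA_real_,
    quantification_basis = "NISP"
  )
  s <- survey_summary(sites)
  expect_equal(s$n_sites, 53L)
  expect_equal(s$quantified_n, 44L)
  expect_equal(round(s$quantified_share_pct), 83)
  expect_equal(round(s$volume_reported_share_pct), 84)
  expect_equal(s$sieved_n, 32L)
  m2 <- s$mesh_shares$share_pct[s$mesh_shares$mesh_mm == 2]
  expect_equal(round(m2, 1), 31.2)
})
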