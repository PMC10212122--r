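# Synthetic regional pools, period catch lists and site assemblages with
# known ground truth. All randomness flows from one integer seed; every
# generated object draws from a sub-seed derived from (seed, object id) so
# objects are independently reproducible.

#' Configuration for the synthetic-assemblage generator
#'
#' Defaults describe a southern-Brazil-like study system: a regional pool
#' of 365 fish species, three period catch lists of 62, 34 and 94 species
#' (the two pre-European periods biased toward large-bodied species, the
#' modern one unselective), site assemblages with total specimen counts
#' between 1e2 and 1e5, sieve retention falling with mesh size, and
#' identification beyond class succeeding for 17% of bony-fish and 56.7%
#' of cartilaginous-fish remains.
#'
#' @param seed Integer master seed.
#' @param n_pool Regional pool size (species).
#' @param n_species_per_period Named integer vector, species per period.
#' @param selectivity Named list, one `c(beta_tl=, beta_logl=)` pair per
#'   period; catch inclusion weight is
#'   `exp(beta_tl * TL + beta_logl * log(Lmax))`, so zeros give uniform
#'   sampling.
#' @param n_sites Number of archaeological sites to simulate.
#' @param total_nisp_range Range (specimens) for per-site totals, drawn
#'   log-uniformly.
#' @param mesh_levels Sieve meshes (mm) cycled across sites.
#' @param retention_midpoint_cm Body size at 50% retention through a 2 mm
#'   mesh; the midpoint scales linearly with mesh size.
#' @param retention_slope Logistic slope on log body size (steeper = closer
#'   to a hard sieve cut-off).
#' @param id_beyond_class_prob Named probabilities that a retained specimen
#'   is identified below class, per fish class.
#' @param sad_sigma Lognormal standard deviation of the species-abundance
#'   distribution within a site.
#' @param r2_target Target squared correlation between log maximum size and
#'   log maximum mass in the pool.
#' @param size_log10_mean,size_log10_sd Normal parameters of log10 maximum
#'   body size (cm).
#' @param mass_intercept,mass_slope Allometric coefficients of
#'   `log10(mass g) = a + b * log10(size cm) + noise`.
#' @param prop_cartilaginous Fraction of taxonomic orders assigned to the
#'   cartilaginous class.
#' @param volume_range Range (m^3) for excavated sediment volumes.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_pool = 365L,
                             n_species_per_period = c(
                               P1 = 62L, P2 = 34L, P3 = 94L
                             ),
                             selectivity = list(
                               P1 = c(beta_tl = 0, beta_logl = 1.5),
                               P2 = c(beta_tl = 0, beta_logl = 1.5),
                               P3 = c(beta_tl = 0, beta_logl = 0)
                             ),
                             n_sites = 12L,
                             total_nisp_range = c(100, 1e5),
                             mesh_levels = c(2, 3, 4, 5),
                             retention_midpoint_cm = 4,
                             retention_slope = 4,
                             id_beyond_class_prob = c(
                               bony = 0.17, cartilaginous = 0.567
                             ),
                             sad_sigma = 1,
                             r2_target = 0.67,
                             size_log10_mean = 1.5,
                             size_log10_sd = 0.35,
                             mass_intercept = -2,
                             mass_slope = 3,
                             prop_cartilaginous = 0.15,
                             volume_range = c(0.06, 13.8)) {
  cfg <- list(
    seed = as.integer(seed), n_pool = as.integer(n_pool),
    n_species_per_period = n_species_per_period,
    selectivity = selectivity, n_sites = as.integer(n_sites),
    total_nisp_range = total_nisp_range, mesh_levels = mesh_levels,
    retention_midpoint_cm = retention_midpoint_cm,
    retention_slope = retention_slope,
    id_beyond_class_prob = id_beyond_class_prob,
    sad_sigma = sad_sigma, r2_target = r2_target,
    size_log10_mean = size_log10_mean, size_log10_sd = size_log10_sd,
    mass_intercept = mass_intercept, mass_slope = mass_slope,
    prop_cartilaginous = prop_cartilaginous, volume_range = volume_range
  )
  if (any(cfg$n_species_per_period > cfg$n_pool)) {
    stop("config error: n_species_per_period may not exceed n_pool",
      call. = FALSE
    )
  }
  probs <- c(cfg$id_beyond_class_prob, cfg$prop_cartilaginous)
  if (any(probs < 0 | probs > 1)) {
    stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$total_nisp_range <= 0)) {
    stop("config error: total NISP must be positive", call. = FALSE)
  }
  if (cfg$r2_target <= 0 || cfg$r2_target > 1) {
    stop("config error: r2_target must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$size_log10_sd <= 0 || cfg$sad_sigma < 0) {
    stop("config error: degenerate variance parameter", call. = FALSE)
  }
  if (!setequal(names(cfg$n_species_per_period), names(cfg$selectivity))) {
    stop("config error: selectivity must name the same periods as ",
      "n_species_per_period",
      call. = FALSE
    )
  }
  structure(cfg, class = "generator_config")
}

#' Derive a reproducible sub-seed for one generated object
#'
#' Hashes the master seed together with an object identifier so each pool,
#' catch or site assemblage has its own independent, replayable stream.
#'
#' @param seed Integer master seed.
#' @param id Character object identifier.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, id) {
  h <- as.double(seed) %% 2147483629
  for (b in as.integer(charToRaw(as.character(id)))) {
    h <- (h * 131 + b) %% 2147483629
  }
  as.integer(h)
}

trophic_group_given_tl <- function(tl, rng_u) {
  # Conditional guild probabilities given trophic level: low TL feeds on
  # plants/plankton, mid TL on invertebrates, high TL on fish.
  probs <- function(tl) {
    if (tl < 2.3) {
      c(herbivore = 0.7, planktivore = 0.3)
    } else if (tl < 3.0) {
      c(omnivore = 0.4, invertivore = 0.35, planktivore = 0.25)
    } else if (tl < 3.8) {
      c(invertivore = 0.6, macrocarnivore = 0.35, omnivore = 0.05)
    } else if (tl < 4.4) {
      c(macrocarnivore = 0.6, piscivore = 0.4)
    } else {
      c(piscivore = 0.8, macrocarnivore = 0.2)
    }
  }
  vapply(seq_along(tl), function(i) {
    p <- probs(tl[i])
    names(p)[findInterval(rng_u[i], cumsum(p), left.open = TRUE) + 1L]
  }, character(1))
}

#' Generate a regional species pool with correlated traits
#'
#' Draws `n_pool` species organised into a genus/family/order hierarchy
#' under the bony and cartilaginous classes. Trophic level follows a
#' scaled Beta(2, 2) on \[2.0, 4.9\]; log10 maximum body size is normal;
#' log10 maximum body mass follows the allometry
#' `a + b * log10(size) + noise`, the noise variance calibrated so the
#' expected squared size-mass correlation equals `r2_target`. Trophic
#' groups are assigned by trophic-level-conditional guild probabilities.
#'
#' @param config A [generator_config()].
#' @return A list with elements `traits` (one row per species) and `taxa`
#'   (records at every rank, class to species, with lineages).
#' @export
generate_species_pool <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(derive_seed(config$seed, "species_pool"))
  n <- config$n_pool

  n_orders <- max(4L, round(n / 60))
  n_cart_orders <- max(1L, round(n_orders * config$prop_cartilaginous))
  order_class <- rep("bony", n_orders)
  order_class[seq_len(n_cart_orders)] <- "cartilaginous"
  class_name <- c(bony = "Actinopterygii", cartilaginous = "Elasmobranchii")
  orders <- sprintf("Order%02d", seq_len(n_orders))

  n_fam <- n_orders * 3L
  fam_order <- rep(seq_len(n_orders), each = 3L)
  families <- sprintf("Family%03d", seq_len(n_fam))
  n_gen <- n_fam * 4L
  gen_family <- rep(seq_len(n_fam), each = 4L)
  genera <- sprintf("Genus%03d", seq_len(n_gen))

  sp_genus <- sample.int(n_gen, n, replace = TRUE)
  species <- sprintf(
    "%s sp%03d", tolower(genera[sp_genus]), seq_len(n)
  )

  tl <- 2.0 + 2.9 * rbeta(n, 2, 2)
  log10_l <- rnorm(n, config$size_log10_mean, config$size_log10_sd)
  r2 <- config$r2_target
  noise_sd <- abs(config$mass_slope) * config$size_log10_sd *
    sqrt((1 - r2) / r2)
  log10_w <- config$mass_intercept + config$mass_slope * log10_l +
    rnorm(n, 0, noise_sd)
  tg <- trophic_group_given_tl(tl, runif(n))

  sp_fish_class <- order_class[fam_order[gen_family[sp_genus]]]
  traits <- tibble::tibble(
    species = species,
    trophic_level = round(pmin(4.9, pmax(2.0, tl)), 2),
    trophic_group = tg,
    max_body_size_cm = pmax(round(10^log10_l, 1), 0.1),
    max_body_mass_g = pmax(round(10^log10_w, 2), 0.01)
  )

  lineage_of <- function(g) {
    f <- gen_family[g]
    o <- fam_order[f]
    c(class_name[[order_class[o]]], orders[o], families[f], genera[g])
  }
  join <- function(x) paste(x, collapse = LINEAGE_SEP)

  taxa_class <- tibble::tibble(
    taxon_id = paste0("class:", unname(class_name[unique(order_class)])),
    name = unname(class_name[unique(order_class)]),
    rank = "class",
    lineage = unname(class_name[unique(order_class)]),
    fish_class = unique(order_class)
  )
  taxa_order <- tibble::tibble(
    taxon_id = paste0("order:", orders),
    name = orders, rank = "order",
    lineage = vapply(seq_len(n_orders), function(o) {
      join(c(class_name[[order_class[o]]], orders[o]))
    }, character(1)),
    fish_class = order_class
  )
  taxa_family <- tibble::tibble(
    taxon_id = paste0("family:", families),
    name = families, rank = "family",
    lineage = vapply(seq_len(n_fam), function(f) {
      o <- fam_order[f]
      join(c(class_name[[order_class[o]]], orders[o], families[f]))
    }, character(1)),
    fish_class = order_class[fam_order]
  )
  taxa_genus <- tibble::tibble(
    taxon_id = paste0("genus:", genera),
    name = genera, rank = "genus",
    lineage = vapply(seq_len(n_gen), function(g) join(lineage_of(g)),
      character(1)
    ),
    fish_class = order_class[fam_order[gen_family]]
  )
  taxa_species <- tibble::tibble(
    taxon_id = paste0("species:", species),
    name = species, rank = "species",
    lineage = vapply(seq_len(n), function(i) {
      join(c(lineage_of(sp_genus[i]), species[i]))
    }, character(1)),
    fish_class = sp_fish_class
  )

  list(
    traits = traits,
    taxa = dplyr::bind_rows(
      taxa_class, taxa_order, taxa_family, taxa_genus, taxa_species
    )
  )
}

#' Draw one period catch list from a species pool
#'
#' Species are sampled without replacement with inclusion weight
#' proportional to `exp(beta_tl * TL + beta_logl * log(Lmax))`. Both
#' coefficients zero gives a uniform random subset; a large `beta_logl`
#' concentrates the catch on the largest-bodied species.
#'
#' @param pool_traits Trait table of the pool (one row per species).
#' @param n_species Number of species to draw.
#' @param selectivity `c(beta_tl=, beta_logl=)`.
#' @param seed Integer seed.
#' @param period_id Label for the resulting catch.
#' @return A tibble with columns `period_id`, `species`.
#' @export
generate_period_catch <- function(pool_traits, n_species,
                                  selectivity = c(beta_tl = 0, beta_logl = 0),
                                  seed = 1L, period_id = "P1") {
  if (n_species > nrow(pool_traits)) {
    stop("n_species exceeds the pool size", call. = FALSE)
  }
  set.seed(seed)
  b_tl <- selectivity[["beta_tl"]]
  b_logl <- selectivity[["beta_logl"]]
  if (is.infinite(b_tl) && is.infinite(b_logl)) {
    stop("at most one selectivity coefficient may be infinite",
      call. = FALSE
    )
  }
  if (is.infinite(b_tl) || is.infinite(b_logl)) {
    # limit case: the catch is exactly the n most extreme species in the
    # infinitely weighted trait; ties broken at random
    key <- if (is.infinite(b_logl)) {
      sign(b_logl) * log(pool_traits$max_body_size_cm)
    } else {
      sign(b_tl) * pool_traits$trophic_level
    }
    ord <- order(key, runif(length(key)), decreasing = TRUE)
    picked <- pool_traits$species[ord[seq_len(n_species)]]
  } else {
    eta <- b_tl * pool_traits$trophic_level +
      b_logl * log(pool_traits$max_body_size_cm)
    w <- exp(eta - max(eta)) # shift-invariant weights, no overflow
    picked <- sample(pool_traits$species, n_species, prob = w)
  }
  tibble::tibble(period_id = period_id, species = picked)
}

sieve_retention_prob <- function(size_cm, mesh_mm, midpoint_cm_2mm, slope) {
  midpoint <- midpoint_cm_2mm * mesh_mm / 2
  plogis(slope * (log(size_cm) - log(midpoint)))
}

#' Simulate the excavated assemblage of one site
#'
#' Allocates `total_nisp` specimens over the catch species by a lognormal
#' species-abundance distribution (multinomial allocation), passes each
#' specimen through a logistic sieve-retention filter in log body size
#' with a mesh-proportional midpoint, then identifies each retained
#' specimen beyond class with the class-specific probability; unidentified
#' specimens are recorded under the class-level taxon (Actinopterygii or
#' Elasmobranchii).
#'
#' @param catch Character vector of species in the site's catch.
#' @param pool A pool as returned by [generate_species_pool()].
#' @param config A [generator_config()].
#' @param site_id Site identifier.
#' @param mesh_mm Sieve mesh (mm); `NA` disables the retention filter.
#' @param total_nisp Total specimens deposited before recovery loss.
#' @param seed Integer seed.
#' @param cultural_phase,latitude,median_age_cal_bp,volume_m3,source_category
#'   Site metadata passed through to the site record.
#' @return A list with `counts` (taxon-level count rows), `site` (site
#'   metadata row) and `truth` (per-species deposited/retained/identified
#'   specimen numbers).
#' @export
generate_site_assemblage <- function(catch, pool, config, site_id,
                                     mesh_mm, total_nisp, seed,
                                     cultural_phase = "Sambaqui",
                                     latitude = -26, median_age_cal_bp = NA,
                                     volume_m3 = NA,
                                     source_category = "A") {
  stopifnot(length(catch) > 0)
  set.seed(seed)
  tr <- pool$traits[match(catch, pool$traits$species), ]
  if (anyNA(tr$species)) {
    stop("catch species missing from the pool trait table", call. = FALSE)
  }

  rel <- rlnorm(length(catch), 0, config$sad_sigma)
  alloc <- as.integer(rmultinom(1, total_nisp, rel / sum(rel)))

  if (is.na(mesh_mm)) {
    p_ret <- rep(1, length(catch))
  } else {
    p_ret <- sieve_retention_prob(
      tr$max_body_size_cm, mesh_mm,
      config$retention_midpoint_cm, config$retention_slope
    )
  }
  retained <- rbinom(length(catch), alloc, p_ret)

  sp_taxa <- pool$taxa[match(catch, pool$taxa$name), ]
  p_id <- config$id_beyond_class_prob[sp_taxa$fish_class]
  identified <- rbinom(length(catch), retained, p_id)
  unidentified <- retained - identified

  class_name <- c(bony = "Actinopterygii", cartilaginous = "Elasmobranchii")
  class_counts <- tapply(
    unidentified, class_name[sp_taxa$fish_class], sum
  )
  class_counts <- class_counts[!is.na(class_counts) & class_counts > 0]

  counts <- dplyr::bind_rows(
    tibble::tibble(
      site_id = site_id, cultural_phase = cultural_phase,
      taxon_id = sp_taxa$taxon_id[identified > 0],
      count = identified[identified > 0]
    ),
    tibble::tibble(
      site_id = site_id, cultural_phase = cultural_phase,
      taxon_id = paste0("class:", names(class_counts)),
      count = as.integer(class_counts)
    )
  )

  site <- tibble::tibble(
    site_id = site_id, name = site_id, latitude = latitude,
    source_category = source_category, mesh_mm = mesh_mm,
    volume_m3 = volume_m3, median_age_cal_bp = median_age_cal_bp,
    quantification_basis = "NISP"
  )
  truth <- tibble::tibble(
    species = catch, deposited = alloc, retention_prob = p_ret,
    retained = retained, identified = identified
  )
  list(counts = counts, site = site, truth = truth)
}

#' Simulate a complete study dataset with known ground truth
#'
#' Runs the full generator: regional pool, one catch list per period, and
#' one excavated assemblage per site. Pre-modern periods are mapped to
#' cultural phases (first period to Sambaqui, second to Taquara-Itarare);
#' the last period stands for the modern survey and receives no
#' archaeological sites. Sites cycle through the configured mesh sizes,
#' draw their total specimen count log-uniformly and their excavated
#' volume uniformly from the configured ranges.
#'
#' @param config A [generator_config()].
#' @return A list with `dataset` (a [catch_dataset()]) and `truth`
#'   (config, pool, catches and per-site specimen histories).
#' @export
simulate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  pool <- generate_species_pool(config)

  period_ids <- names(config$n_species_per_period)
  catches <- lapply(period_ids, function(p) {
    generate_period_catch(
      pool$traits, config$n_species_per_period[[p]],
      config$selectivity[[p]],
      seed = derive_seed(config$seed, paste0("catch_", p)),
      period_id = p
    )
  })
  periods <- dplyr::bind_rows(catches)

  n_periods_arch <- max(1L, length(period_ids) - 1L)
  phase_of <- c("Sambaqui", "Taquara-Itarare")
  set.seed(derive_seed(config$seed, "site_layout"))
  site_period <- rep_len(seq_len(n_periods_arch), config$n_sites)
  meshes <- rep_len(config$mesh_levels, config$n_sites)
  lat <- runif(config$n_sites, -31.5, -25)
  vol <- runif(config$n_sites, config$volume_range[1], config$volume_range[2])
  lt <- log10(config$total_nisp_range)
  nisp_tot <- round(10^runif(config$n_sites, lt[1], lt[2]))
  age_rng <- list(c(1150, 4500), c(600, 1050))
  ages <- vapply(site_period, function(p) {
    r <- age_rng[[min(p, 2L)]]
    round(runif(1, r[1], r[2]) / 50) * 50
  }, numeric(1))

  sims <- lapply(seq_len(config$n_sites), function(i) {
    pid <- period_ids[site_period[i]]
    generate_site_assemblage(
      catch = periods$species[periods$period_id == pid],
      pool = pool, config = config,
      site_id = sprintf("site%02d", i), mesh_mm = meshes[i],
      total_nisp = nisp_tot[i],
      seed = derive_seed(config$seed, sprintf("site%02d", i)),
      cultural_phase = phase_of[min(site_period[i], 2L)],
      latitude = lat[i], median_age_cal_bp = ages[i], volume_m3 = vol[i]
    )
  })

  dataset <- catch_dataset(
    taxa = pool$taxa,
    sites = dplyr::bind_rows(lapply(sims, `[[`, "site")),
    counts = dplyr::bind_rows(lapply(sims, `[[`, "counts")),
    traits = pool$traits,
    periods = periods
  )
  truth <- list(
    config = config, pool = pool, catches = catches,
    sites = lapply(sims, `[[`, "truth")
  )
  list(dataset = dataset, truth = truth)
}
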