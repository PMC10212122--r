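# End-to-end orchestration: validate -> (simulate | load) -> abundance ->
# recovery -> traits, with a self-describing JSON manifest. The functions
# here are the programmatic entry point; thin wrappers around them (or an
# Rscript) can expose shell subcommands where needed.

#' Build a run configuration
#'
#' @param data_dir Directory holding the five input CSVs; `NULL` to
#'   simulate instead.
#' @param simulate A [generator_config()] used when `data_dir` is `NULL`.
#' @param out_dir Output directory for tables and the manifest.
#' @param reps Null-model repetitions (>= 1).
#' @param seed Integer seed for the analysis stages.
#' @param traits_to_test Trait columns run through the null model.
#' @return A `run_config` list.
#' @export
run_config <- function(data_dir = NULL,
                       simulate = generator_config(),
                       out_dir = tempfile("paleocatch_run_"),
                       reps = 1000L,
                       seed = 20230525L,
                       traits_to_test = c(
                         "trophic_level", "max_body_size_cm",
                         "max_body_mass_g"
                       )) {
  stopifnot(reps >= 1L)
  structure(
    list(
      data_dir = data_dir, simulate = simulate, out_dir = out_dir,
      reps = as.integer(reps), seed = as.integer(seed),
      traits_to_test = traits_to_test
    ),
    class = "run_config"
  )
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

assemblage_table <- function(dataset) {
  dplyr::distinct(dataset$counts, .data$site_id, .data$cultural_phase)
}

per_assemblage_metrics <- function(dataset) {
  asm <- assemblage_table(dataset)
  rows <- lapply(seq_len(nrow(asm)), function(i) {
    sub <- dataset$counts[
      dataset$counts$site_id == asm$site_id[i] &
        dataset$counts$cultural_phase == asm$cultural_phase[i],
    ]
    sub <- aggregate_counts(sub, dataset$sites)
    site <- dataset$sites[dataset$sites$site_id == asm$site_id[i], ]
    summ <- suppressWarnings(relative_abundance(sub, dataset$taxa))
    dens <- suppressMessages(nisp_density(sub, site))
    tibble::tibble(
      site_id = asm$site_id[i],
      cultural_phase = asm$cultural_phase[i],
      latitude = site$latitude[1],
      median_age_cal_bp = site$median_age_cal_bp[1],
      mesh_mm = site$mesh_mm[1],
      total_nisp = summ$total_nisp,
      identified_nisp = summ$identified_nisp,
      sr_mlti = species_richness_mlti(sub, dataset$taxa),
      nisp_per_m3 = dens,
      sr_per_nisp = sr_per_nisp(sub, dataset$taxa),
      watl = suppressWarnings(watl(sub, dataset$taxa, dataset$traits))
    )
  })
  dplyr::bind_rows(rows)
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) a dataset, validates it, and writes the
#' assemblage metrics, mesh-class recovery diagnostics, SR~NISP
#' correlations and per-trait null-model summaries to CSV, together with
#' a JSON manifest recording the configuration, seed, package version and
#' MD5 checksum of every output so a run is fully self-describing and
#' replayable.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(config$data_dir)) {
    log_stage("simulate", "generating synthetic dataset (seed %d)",
      config$simulate$seed)
    sim <- simulate_dataset(config$simulate)
    dataset <- sim$dataset
  } else {
    log_stage("load", "reading dataset from %s", config$data_dir)
    dataset <- read_dataset(
      file.path(config$data_dir, "taxa.csv"),
      file.path(config$data_dir, "sites.csv"),
      file.path(config$data_dir, "counts.csv"),
      file.path(config$data_dir, "traits.csv"),
      file.path(config$data_dir, "periods.csv")
    )
  }

  log_stage("validate", "checking invariants")
  violations <- validate_dataset(dataset)
  if (nrow(violations) > 0L) {
    stop(
      sprintf(
        "stage 'validate' failed: %d violation(s); first: [%s] %s: %s",
        nrow(violations), violations$table[1], violations$record_id[1],
        violations$message[1]
      ),
      call. = FALSE
    )
  }

  outputs <- character()
  emit <- function(df, name) {
    p <- file.path(config$out_dir, paste0(name, ".csv"))
    readr::write_csv(df, p, na = "")
    outputs[[name]] <<- p
    p
  }

  log_stage("abundance", "per-assemblage metrics")
  metrics <- per_assemblage_metrics(dataset)
  emit(metrics, "assemblage_metrics")

  log_stage("recovery", "mesh-size diagnostics")
  recovery <- list()
  for (metric in c("nisp_per_m3", "sr_per_nisp")) {
    v <- setNames(metrics[[metric]], metrics$site_id)
    groups <- mesh_class_groups(dataset$sites, v)
    groups <- groups[lengths(groups) >= 2L]
    if (length(groups) >= 2L) {
      at <- anova_tukey(groups)
      recovery[[metric]] <- tibble::tibble(
        metric = metric, comparison = at$tukey$comparison,
        diff = at$tukey$diff, p_adj = at$tukey$p_adj,
        f = at$f, p_overall = at$p
      )
    }
  }
  if (length(recovery) > 0L) {
    emit(dplyr::bind_rows(recovery), "mesh_anova_tukey")
  }
  ok <- is.finite(metrics$sr_mlti) & is.finite(metrics$nisp_per_m3)
  if (sum(ok) >= 4L) {
    cor_all <- pearson_sr_nisp(metrics$sr_mlti[ok], metrics$nisp_per_m3[ok])
    sens <- endmember_sensitivity(
      metrics$sr_mlti[ok], metrics$nisp_per_m3[ok]
    )
    emit(
      tibble::tibble(
        subset = c("all", "all_minus_endmember"),
        r = c(cor_all$r, sens$without$r),
        p = c(cor_all$p, sens$without$p),
        n = c(cor_all$n, sens$without$n)
      ),
      "sr_nisp_correlation"
    )
  }

  log_stage("traits", "null model, %d reps", config$reps)
  pool <- build_total_pool(
    dataset$periods, dataset$traits$species, dataset$traits
  )
  period_ids <- unique(dataset$periods$period_id)
  null_rows <- list()
  prop_rows <- list()
  for (pid in period_ids) {
    catch <- dataset$periods$species[dataset$periods$period_id == pid]
    for (trait in config$traits_to_test) {
      res <- trait_null_test(
        catch, pool, dataset$traits, trait,
        reps = config$reps,
        seed = derive_seed(config$seed, paste0("null_", pid, "_", trait)),
        period_id = pid
      )
      null_rows[[paste(pid, trait)]] <- tibble::tibble(
        period = pid, trait = trait, n_species = length(catch),
        observed_mean = res$observed_mean, null_mean = res$null_mean,
        statistic = res$statistic, p = res$p, reps = res$reps,
        seed = res$seed, mode = res$mode
      )
    }
    for (by in c("size_class", "trophic_group", "functional_entity")) {
      pr <- proportion_by_category(catch, dataset$traits, by = by)
      pr$period <- pid
      pr$classifier <- by
      prop_rows[[paste(pid, by)]] <- pr
    }
  }
  emit(dplyr::bind_rows(null_rows), "trait_null_tests")
  emit(dplyr::bind_rows(prop_rows), "trait_proportions")

  anova_rows <- lapply(config$traits_to_test, function(trait) {
    at <- across_period_anova(dataset$periods, dataset$traits, trait)
    tibble::tibble(
      trait = trait, comparison = at$tukey$comparison,
      diff = at$tukey$diff, p_adj = at$tukey$p_adj,
      f = at$f, p_overall = at$p
    )
  })
  emit(dplyr::bind_rows(anova_rows), "trait_period_anova")

  mintl <- tibble::tibble(
    period = period_ids,
    min_tl = vapply(period_ids, function(pid) {
      min_trophic_level(
        dataset$periods$species[dataset$periods$period_id == pid],
        dataset$traits
      )
    }, numeric(1))
  )
  emit(mintl, "min_trophic_level")

  manifest <- list(
    package_version = as.character(utils::packageVersion("paleocatch")),
    seed = config$seed,
    reps = config$reps,
    simulated = is.null(config$data_dir),
    config = config[c("data_dir", "reps", "seed", "traits_to_test")],
    generator = if (is.null(config$data_dir)) {
      unclass(config$simulate)
    },
    pool = list(
      n_pool = pool$n_pool, n_targets = pool$n_targets,
      n_non_targets = pool$n_non_targets
    ),
    outputs = lapply(outputs, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(
    manifest, manifest_path,
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
  )
  log_stage("report", "wrote %d tables + manifest to %s",
    length(outputs), config$out_dir)
  invisible(manifest)
}
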