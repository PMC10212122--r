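# Null-model comparison of catch traits against the regional species
# pool, across-period ANOVA/Tukey, size-class / trophic-group /
# functional-entity proportions and exact two-tailed binomial tests.

SIZE_CLASS_LABELS <- c(
  "<7", "7-15.0", "15.1-30.0", "30.1-50.0", "50.1-80.0", ">80"
)
LOG_TRAITS <- c("max_body_size_cm", "max_body_mass_g")

#' Build the total regional species pool
#'
#' The pool is the union of every period's catch list (the targets) with
#' the regional species never recorded as targets; it represents the
#' region's full richness and trait variability irrespective of period.
#' Any overlap between catches and the regional list is absorbed by the
#' union and reported.
#'
#' @param periods Period table (`period_id`, `species`).
#' @param regional_species Character vector of regional non-target (or
#'   all regional) species.
#' @param traits Optional trait table; when given, every pool species
#'   must have a trait record.
#' @return A list of class `species_pool`: `pool`, `targets`,
#'   `non_targets`, `n_pool`, `n_targets`, `n_non_targets`, `n_overlap`.
#' @export
build_total_pool <- function(periods, regional_species, traits = NULL) {
  targets <- sort(unique(periods$species))
  regional_species <- sort(unique(regional_species))
  pool <- union(targets, regional_species)
  if (!is.null(traits)) {
    missing <- setdiff(pool, traits$species)
    if (length(missing) > 0L) {
      stop(
        sprintf(
          "species without trait records: %s",
          paste(sQuote(head(missing, 10L)), collapse = ", ")
        ),
        call. = FALSE
      )
    }
  }
  structure(
    list(
      pool = sort(pool),
      targets = targets,
      non_targets = setdiff(regional_species, targets),
      n_pool = length(pool),
      n_targets = length(targets),
      n_non_targets = length(setdiff(regional_species, targets)),
      n_overlap = length(intersect(targets, regional_species))
    ),
    class = "species_pool"
  )
}

#' @export
print.species_pool <- function(x, ...) {
  cat(sprintf(
    "<species_pool> %d species (%d targets + %d non-targets, overlap %d)\n",
    x$n_pool, x$n_targets, x$n_non_targets, x$n_overlap
  ))
  invisible(x)
}

#' Draw random richness-matched assemblages from the pool
#'
#' Each of `reps` draws samples `n` species uniformly without replacement
#' from the pool; draws are mutually independent. These are the null
#' assemblages against which an observed catch is compared.
#'
#' @param pool Character vector of pool species (or a `species_pool`).
#' @param n Species per draw.
#' @param reps Number of draws (default 1000).
#' @param seed Integer seed.
#' @return A `reps x n` character matrix of species names, with
#'   attributes `seed` and `reps`.
#' @export
draw_null <- function(pool, n, reps = 1000L, seed = 20230525L) {
  if (inherits(pool, "species_pool")) pool <- pool$pool
  if (n > length(pool)) {
    stop("null sample size exceeds the pool size", call. = FALSE)
  }
  stopifnot(reps >= 1L)
  set.seed(seed)
  draws <- matrix("", nrow = reps, ncol = n)
  for (r in seq_len(reps)) {
    draws[r, ] <- sample(pool, n)
  }
  attr(draws, "seed") <- seed
  attr(draws, "reps") <- reps
  draws
}

#' Trait values of null draws
#'
#' @param draws Matrix from [draw_null()].
#' @param traits Trait table.
#' @param trait Trait column name.
#' @param log_transform Log the values (natural log)?
#' @return Numeric matrix, same shape as `draws`.
#' @export
null_trait_values <- function(draws, traits, trait, log_transform = FALSE) {
  v <- traits[[trait]][match(as.vector(draws), traits$species)]
  if (anyNA(v)) {
    stop("null draw contains species without trait records", call. = FALSE)
  }
  if (log_transform) v <- log(v)
  matrix(v, nrow = nrow(draws), ncol = ncol(draws))
}

#' Compare observed trait values against null draws
#'
#' Default mode (`"pooled_t"`): a Welch two-sample two-sided t-test of the
#' observed values against all null values pooled across draws. The
#' alternative mode (`"null_means"`) locates the observed mean within the
#' distribution of per-draw null means and doubles the smaller tail
#' (add-one empirical p), making no distributional assumption.
#'
#' @param observed Numeric vector of observed trait values (>= 2).
#' @param null_values Numeric matrix of null trait values (reps x n).
#' @param mode `"pooled_t"` or `"null_means"`.
#' @return A list: `p` (two-sided), `statistic`, `observed_mean`,
#'   `null_mean`, `mode`.
#' @export
observed_vs_null_test <- function(observed, null_values,
                                  mode = c("pooled_t", "null_means")) {
  mode <- match.arg(mode)
  stopifnot(length(observed) >= 2L, is.matrix(null_values))
  nullv <- as.vector(null_values)
  if (var(observed) == 0 && var(nullv) == 0) {
    stop("zero variance in both observed and null values", call. = FALSE)
  }
  if (mode == "pooled_t") {
    tt <- t.test(observed, nullv, alternative = "two.sided")
    out <- list(
      p = tt$p.value, statistic = unname(tt$statistic),
      observed_mean = mean(observed), null_mean = mean(nullv),
      mode = mode
    )
  } else {
    null_means <- rowMeans(null_values)
    obs_mean <- mean(observed)
    r <- length(null_means)
    p_low <- (sum(null_means <= obs_mean) + 1) / (r + 1)
    p_high <- (sum(null_means >= obs_mean) + 1) / (r + 1)
    out <- list(
      p = min(1, 2 * min(p_low, p_high)),
      statistic = (obs_mean - mean(null_means)) / sd(null_means),
      observed_mean = obs_mean, null_mean = mean(null_means),
      mode = mode
    )
  }
  out
}

#' Full null-model test of one trait in one period
#'
#' Convenience wrapper: extracts the period's observed trait values,
#' draws richness-matched null assemblages from the pool, and runs
#' [observed_vs_null_test()]. Maximum body size and mass are analysed on
#' the natural-log scale; trophic level raw.
#'
#' @param catch Character vector of the period's species.
#' @param pool A `species_pool` or character vector.
#' @param traits Trait table.
#' @param trait Trait column name.
#' @param reps Number of null draws (default 1000).
#' @param seed Integer seed (default 20230525).
#' @param mode Test mode, see [observed_vs_null_test()].
#' @param period_id Label stored in the result.
#' @return A list of class `null_model_result`: `trait`, `period`,
#'   `observed`, `null_values`, `p`, `statistic`, `observed_mean`,
#'   `null_mean`, `reps`, `seed`, `mode`.
#' @export
trait_null_test <- function(catch, pool, traits, trait,
                            reps = 1000L, seed = 20230525L,
                            mode = c("pooled_t", "null_means"),
                            period_id = NA_character_) {
  mode <- match.arg(mode)
  log_tr <- trait %in% LOG_TRAITS
  obs <- traits[[trait]][match(catch, traits$species)]
  if (anyNA(obs)) {
    stop(
      sprintf(
        "catch species without trait records: %s",
        paste(sQuote(head(catch[is.na(obs)], 10L)), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  if (log_tr) obs <- log(obs)
  draws <- draw_null(pool, length(catch), reps = reps, seed = seed)
  nulls <- null_trait_values(draws, traits, trait, log_transform = log_tr)
  test <- observed_vs_null_test(obs, nulls, mode = mode)
  structure(
    c(
      list(
        trait = trait, period = period_id, observed = obs,
        null_values = nulls, reps = reps, seed = seed
      ),
      test
    ),
    class = "null_model_result"
  )
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf(
    "<null_model_result> %s, period %s: observed mean %.3f vs null %.3f, p = %.4g (%s, %d reps)\n",
    x$trait, x$period, x$observed_mean, x$null_mean, x$p, x$mode, x$reps
  ))
  invisible(x)
}

#' Across-period trait comparison (ANOVA + Tukey HSD)
#'
#' Compares one trait across the period catch lists with one-way ANOVA
#' followed by Tukey HSD. Size and mass are log-transformed before
#' analysis; trophic level is analysed raw.
#'
#' @param periods Period table (`period_id`, `species`).
#' @param traits Trait table.
#' @param trait Trait column name.
#' @return An `anova_tukey` result.
#' @export
across_period_anova <- function(periods, traits, trait) {
  log_tr <- trait %in% LOG_TRAITS
  groups <- lapply(split(periods$species, periods$period_id), function(sp) {
    v <- traits[[trait]][match(sp, traits$species)]
    if (anyNA(v)) {
      stop("period species without trait records", call. = FALSE)
    }
    if (log_tr) log(v) else v
  })
  anova_tukey(groups)
}

#' Maximum-body-size class of a species
#'
#' Bins maximum total length (cm) into the six classes `<7`, `7-15.0`,
#' `15.1-30.0`, `30.1-50.0`, `50.1-80.0` and `>80`. The printed labels
#' are one-decimal bins, so breaks are upper-inclusive: 15.0 falls in
#' `7-15.0`, 30.0 in `15.1-30.0`, 30.05 in `30.1-50.0`.
#'
#' @param max_body_size_cm Positive numeric vector.
#' @return Factor with the six size-class labels.
#' @export
size_class <- function(max_body_size_cm) {
  x <- max_body_size_cm
  if (any(!is.na(x) & x <= 0)) {
    stop("body size must be strictly positive", call. = FALSE)
  }
  out <- rep(NA_character_, length(x))
  out[x < 7] <- SIZE_CLASS_LABELS[1]
  out[x >= 7 & x <= 15] <- SIZE_CLASS_LABELS[2]
  out[x > 15 & x <= 30] <- SIZE_CLASS_LABELS[3]
  out[x > 30 & x <= 50] <- SIZE_CLASS_LABELS[4]
  out[x > 50 & x <= 80] <- SIZE_CLASS_LABELS[5]
  out[x > 80] <- SIZE_CLASS_LABELS[6]
  factor(out, levels = SIZE_CLASS_LABELS)
}

#' Functional entity of a species
#'
#' The pairing of trophic group and maximum-body-size class; with six
#' guilds and six size classes at most 36 entities exist.
#'
#' @param trophic_group Character vector of guilds.
#' @param size_class Size-class labels (factor or character).
#' @return Character vector `"guild|size"`.
#' @export
functional_entity <- function(trophic_group, size_class) {
  paste(trophic_group, as.character(size_class), sep = "|")
}

#' Category proportions within a period catch
#'
#' Tallies a period's species by size class, trophic group or functional
#' entity and expresses each category as a percentage of the period's
#' species count (percentages sum to 100).
#'
#' @param catch Character vector of the period's species.
#' @param traits Trait table.
#' @param by `"size_class"`, `"trophic_group"` or
#'   `"functional_entity"`.
#' @return A tibble: `category`, `n`, `percent`.
#' @export
proportion_by_category <- function(catch, traits,
                                   by = c(
                                     "size_class", "trophic_group",
                                     "functional_entity"
                                   )) {
  by <- match.arg(by)
  idx <- match(catch, traits$species)
  if (anyNA(idx)) {
    stop(
      sprintf(
        "unclassifiable species: %s",
        paste(sQuote(catch[is.na(idx)]), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  cat_of <- switch(by,
    size_class = as.character(size_class(traits$max_body_size_cm[idx])),
    trophic_group = traits$trophic_group[idx],
    functional_entity = functional_entity(
      traits$trophic_group[idx],
      size_class(traits$max_body_size_cm[idx])
    )
  )
  tab <- table(cat_of)
  tibble::tibble(
    category = names(tab),
    n = as.integer(tab),
    percent = 100 * as.integer(tab) / length(catch)
  )
}

#' Exact two-tailed binomial test (minimum-likelihood method)
#'
#' Computes the exact two-tailed p-value for `k` successes in `n` trials
#' under success probability `p0`: the sum of the probabilities of every
#' outcome whose likelihood under Binomial(n, p0) does not exceed that of
#' the observed `k` (with a tiny relative tolerance absorbing floating-
#' point ties). Used for comparing category proportions between periods,
#' with `p0` taken from the comparison period's observed proportion.
#'
#' @param k Observed successes (0..n).
#' @param n Number of trials.
#' @param p0 Null success probability, strictly inside (0, 1).
#' @return The two-tailed p-value, in (0, 1].
#' @export
binomial_two_tailed <- function(k, n, p0) {
  if (p0 <= 0 || p0 >= 1) {
    stop("p0 must lie strictly inside (0, 1)", call. = FALSE)
  }
  stopifnot(k >= 0, k <= n, n >= 1)
  d <- dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}

#' Minimum trophic level of a period catch
#'
#' @param catch Character vector of the period's species.
#' @param traits Trait table.
#' @return The minimum trophic level over the catch.
#' @export
min_trophic_level <- function(catch, traits) {
  stopifnot(length(catch) > 0)
  v <- traits$trophic_level[match(catch, traits$species)]
  min(v, na.rm = TRUE)
}
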