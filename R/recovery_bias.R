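# Second-order-change diagnostics: sieve mesh-size effects on NISP/m^3 and
# SR/NISP, and the SR ~ NISP correlation with endmember sensitivity.

MESH_CLASSES <- c("2-3 mm", "4 mm", "5 mm")

#' Collapse a sieve mesh size into its analysis class
#'
#' The 2 and 3 mm meshes are pooled (both are adequate for recovering fish
#' remains); 4 mm and 5 mm stand alone.
#'
#' @param mesh_mm Numeric vector of mesh sizes in mm (2, 3, 4 or 5).
#' @return Character vector of class labels `"2-3 mm"`, `"4 mm"`,
#'   `"5 mm"`.
#' @export
mesh_class <- function(mesh_mm) {
  bad <- !is.na(mesh_mm) & !mesh_mm %in% c(2, 3, 4, 5)
  if (any(bad)) {
    stop(
      sprintf(
        "unsupported mesh size(s): %s (expected 2, 3, 4 or 5 mm)",
        paste(unique(mesh_mm[bad]), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  out <- rep(NA_character_, length(mesh_mm))
  out[mesh_mm %in% c(2, 3)] <- "2-3 mm"
  out[mesh_mm == 4] <- "4 mm"
  out[mesh_mm == 5] <- "5 mm"
  out
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Classic fixed-effects one-way ANOVA followed by Tukey's honest
#' significant differences on the studentized-range distribution, with the
#' Tukey-Kramer adjustment for unbalanced group sizes and a 95%
#' family-wise confidence level. Used to compare recovery metrics across
#' mesh classes and trait values across time periods.
#'
#' @param groups Named list mapping group label to a numeric vector
#'   (every group needs >= 2 values).
#' @return A list of class `anova_tukey`: `f`, `p`, `df_between`,
#'   `df_within`, `tukey` (tibble with `comparison`, `diff`, `lwr`,
#'   `upr`, `p_adj`).
#' @export
anova_tukey <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop(
      sprintf(
        "group(s) with fewer than 2 values: %s",
        paste(names(groups)[sizes < 2L], collapse = ", ")
      ),
      call. = FALSE
    )
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes))
  )
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 0.95)$group
  structure(
    list(
      f = an["group", "F value"],
      p = an["group", "Pr(>F)"],
      df_between = an["group", "Df"],
      df_within = an["Residuals", "Df"],
      tukey = tibble::tibble(
        comparison = rownames(tk),
        diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
        p_adj = tk[, "p adj"]
      )
    ),
    class = "anova_tukey"
  )
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf(
    "<anova_tukey> F(%d, %d) = %.3f, p = %.4f\n",
    x$df_between, x$df_within, x$f, x$p
  ))
  tk <- x$tukey
  for (i in seq_len(nrow(tk))) {
    cat(sprintf(
      "  %-18s diff = %8.3f  p_adj = %.4f\n",
      tk$comparison[i], tk$diff[i], tk$p_adj[i]
    ))
  }
  invisible(x)
}

#' Mesh-class table of a recovery metric
#'
#' Collects one metric value per sieved site, grouped by mesh class,
#' ready for [anova_tukey()].
#'
#' @param sites Site table (only rows with a mesh size are used).
#' @param values Named numeric vector, metric value per `site_id`.
#' @return Named list mapping mesh class to metric values.
#' @export
mesh_class_groups <- function(sites, values) {
  sieved <- sites[!is.na(sites$mesh_mm), ]
  cls <- mesh_class(sieved$mesh_mm)
  v <- values[sieved$site_id]
  keep <- !is.na(v)
  split(unname(v[keep]), cls[keep])
}

#' Pearson correlation between richness and specimen density
#'
#' Tests the sample-size effect: all else equal, species richness should
#' rise with the density of recovered specimens.
#'
#' @param sr Numeric vector of species richness values.
#' @param nisp Numeric vector of NISP/m^3 (same length).
#' @return A list: `r`, `p` (two-sided, t-based), `n`.
#' @export
pearson_sr_nisp <- function(sr, nisp) {
  keep <- is.finite(sr) & is.finite(nisp)
  sr <- sr[keep]
  nisp <- nisp[keep]
  if (length(sr) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(sr) == 0 || sd(nisp) == 0) {
    stop("zero variance in SR or NISP; correlation undefined", call. = FALSE)
  }
  ct <- cor.test(sr, nisp, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(sr))
}

#' Sensitivity of a correlation to its endmember point
#'
#' Identifies the endmember — the observation simultaneously maximal in
#' both variables — and reports the correlation with and without it. When
#' no point is maximal in both coordinates the point with the largest
#' Mahalanobis distance from the centroid is used instead (flagged), or an
#' error is raised if that fallback is disabled.
#'
#' @param sr,nisp Numeric vectors (>= 4 complete pairs).
#' @param fallback Use the Mahalanobis fallback when no joint maximum
#'   exists (default `TRUE`).
#' @return A list: `with` and `without` (each `r`, `p`, `n`),
#'   `endmember_index` (into the complete pairs), `flagged` (`TRUE` when
#'   the fallback was used).
#' @export
endmember_sensitivity <- function(sr, nisp, fallback = TRUE) {
  keep <- is.finite(sr) & is.finite(nisp)
  sr <- sr[keep]
  nisp <- nisp[keep]
  if (length(sr) < 4L) stop("need at least 4 complete pairs", call. = FALSE)

  idx <- which(sr == max(sr) & nisp == max(nisp))
  flagged <- FALSE
  if (length(idx) != 1L) {
    if (!fallback) {
      stop("no unique point maximal in both variables", call. = FALSE)
    }
    flagged <- TRUE
    m <- cbind(sr, nisp)
    idx <- which.max(mahalanobis(m, colMeans(m), stats::cov(m)))
  }
  list(
    with = pearson_sr_nisp(sr, nisp),
    without = pearson_sr_nisp(sr[-idx], nisp[-idx]),
    endmember_index = idx,
    flagged = flagged
  )
}
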