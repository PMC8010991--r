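# Half-sib quantitative genetics: REML variance components (via lme4),
# heritability, genetic/phenotypic correlations, jackknife standard errors,
# BLUP family breeding values, realized gain and multi-trait selection.

fit_lmm <- function(df) {
  has_rep <- length(unique(df$rep)) > 1L
  form <- if (has_rep) y ~ rep + (1 | fam) else y ~ (1 | fam)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = df, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(sigma2_f = vc$vcov[vc$grp == "fam"],
       sigma2_e = vc$vcov[vc$grp == "Residual"],
       loglik = as.numeric(logLik(fit)),
       fit = fit)
}

#' Univariate REML variance components for a half-sib trial
#'
#' Fits `trait = grand mean + replication (fixed) + family (random) +
#' residual` by REML and returns the family and residual variance
#' components. The family variance is bounded at zero by the estimator; a
#' `truncated` flag marks boundary fits.
#'
#' @param data Tibble with the trait column plus family and replication
#'   label columns.
#' @param trait Name of the trait column.
#' @param family,replication Names of the label columns.
#' @return One-row tibble: `trait`, `sigma2_f`, `sigma2_e`, `n_families`,
#'   `n_per_family`, `loglik`, `truncated`.
#' @export
fit_univariate_reml <- function(data, trait, family = "family_id",
                                replication = "replication_id") {
  if (!trait %in% names(data)) stop_schema(sprintf("No column `%s`.", trait))
  df <- data.frame(y = as.numeric(data[[trait]]),
                   fam = factor(data[[family]]),
                   rep = factor(data[[replication]]))
  if (nlevels(df$fam) < 2L) {
    stop_invalid("Variance components need at least 2 families.")
  }
  res <- fit_lmm(df)
  tibble(trait = trait, sigma2_f = res$sigma2_f, sigma2_e = res$sigma2_e,
         n_families = nlevels(df$fam),
         n_per_family = nrow(df) / nlevels(df$fam),
         loglik = res$loglik,
         truncated = res$sigma2_f < 1e-10)
}

#' Family and residual covariance between two traits
#'
#' Uses the sum-trait identity `cov(i, j) = (var(i + j) - var(i) -
#' var(j)) / 2` applied to univariate REML fits of trait i, trait j and
#' their sum -- exactly equivalent to bivariate REML for balanced designs.
#'
#' @param data Tibble with both trait columns and labels.
#' @param trait_i,trait_j Trait column names.
#' @inheritParams fit_univariate_reml
#' @return One-row tibble: `trait_i`, `trait_j`, `cov_f`, `cov_e`.
#' @export
fit_pair_covariance <- function(data, trait_i, trait_j,
                                family = "family_id",
                                replication = "replication_id") {
  for (tr in c(trait_i, trait_j)) {
    if (!tr %in% names(data)) stop_schema(sprintf("No column `%s`.", tr))
  }
  data$.sum <- as.numeric(data[[trait_i]]) + as.numeric(data[[trait_j]])
  vi <- fit_univariate_reml(data, trait_i, family, replication)
  vj <- fit_univariate_reml(data, trait_j, family, replication)
  vs <- fit_univariate_reml(data, ".sum", family, replication)
  tibble(trait_i = trait_i, trait_j = trait_j,
         cov_f = (vs$sigma2_f - vi$sigma2_f - vj$sigma2_f) / 2,
         cov_e = (vs$sigma2_e - vi$sigma2_e - vj$sigma2_e) / 2)
}

#' Narrow-sense heritability of a half-sib family trial
#'
#' `h2 = k * sigma2_f / (sigma2_f + sigma2_e)`. The multiplier defaults to
#' 2.5, a conservative choice between pure half-sib theory (k = 4) and full
#' sibs, guarding against part-sibling assembly and inbreeding in
#' open-pollinated families; classic k = 4 is selectable.
#'
#' @param vc Variance-components tibble from [fit_univariate_reml()] (or any
#'   data frame with `sigma2_f`, `sigma2_e`).
#' @param k Heritability multiplier.
#' @return Numeric heritability, one value per row of `vc`.
#' @export
heritability <- function(vc, k = 2.5) {
  tot <- vc$sigma2_f + vc$sigma2_e
  if (any(tot <= 0)) stop_degenerate("Total variance must be positive.")
  k * vc$sigma2_f / tot
}

#' Genetic correlation between two traits
#'
#' `r_g = cov_f / sqrt(sigma2_f(i) * sigma2_f(j))` -- the product-form
#' denominator, under which a trait's correlation with itself is exactly 1.
#'
#' @param pc Pair-covariance tibble from [fit_pair_covariance()].
#' @param vc_i,vc_j Variance-components rows for the two traits.
#' @return Numeric correlation.
#' @export
genetic_correlation <- function(pc, vc_i, vc_j) {
  if (vc_i$sigma2_f <= 0 || vc_j$sigma2_f <= 0) {
    stop_degenerate("Genetic correlation undefined with zero family variance.")
  }
  pc$cov_f / sqrt(vc_i$sigma2_f * vc_j$sigma2_f)
}

#' Phenotypic correlation between two traits
#'
#' `r_p = (cov_f + cov_e) / sqrt((sigma2_f(i) + sigma2_e(i)) *
#' (sigma2_f(j) + sigma2_e(j)))`.
#'
#' @inheritParams genetic_correlation
#' @return Numeric correlation.
#' @export
phenotypic_correlation <- function(pc, vc_i, vc_j) {
  ti <- vc_i$sigma2_f + vc_i$sigma2_e
  tj <- vc_j$sigma2_f + vc_j$sigma2_e
  if (ti <= 0 || tj <= 0) {
    stop_degenerate("Phenotypic correlation undefined with zero total variance.")
  }
  (pc$cov_f + pc$cov_e) / sqrt(ti * tj)
}

#' Delete-one-family jackknife standard error
#'
#' Families are the independent genetic units, so the jackknife deletes one
#' family at a time, recomputes the statistic, and returns
#' `sqrt((m - 1)/m * sum((theta_i - mean)^2))` over the m successful
#' leave-one-out subsets. Subsets where the statistic is undefined are
#' skipped with a warning.
#'
#' @param data Tibble with trait and label columns.
#' @param statistic One of `"h2"`, `"r_g"`, `"r_p"`, `"mean"`.
#' @param trait Trait name (for `h2` and `mean`).
#' @param trait_i,trait_j Trait names (for correlations).
#' @param k Heritability multiplier (for `h2`).
#' @inheritParams fit_univariate_reml
#' @return Numeric standard error.
#' @export
jackknife_se <- function(data, statistic, trait = NULL, trait_i = NULL,
                         trait_j = NULL, k = 2.5, family = "family_id",
                         replication = "replication_id") {
  fams <- unique(data[[family]])
  if (length(fams) < 3L) stop_invalid("Jackknife needs at least 3 families.")
  stat_fn <- switch(statistic,
    mean = function(d) mean(d[[trait]]),
    h2 = function(d) heritability(fit_univariate_reml(d, trait, family, replication), k),
    r_g = function(d) {
      vi <- fit_univariate_reml(d, trait_i, family, replication)
      vj <- fit_univariate_reml(d, trait_j, family, replication)
      genetic_correlation(fit_pair_covariance(d, trait_i, trait_j, family, replication),
                          vi, vj)
    },
    r_p = function(d) {
      vi <- fit_univariate_reml(d, trait_i, family, replication)
      vj <- fit_univariate_reml(d, trait_j, family, replication)
      phenotypic_correlation(fit_pair_covariance(d, trait_i, trait_j, family, replication),
                             vi, vj)
    },
    stop_invalid(sprintf("Unknown statistic `%s`.", statistic))
  )
  theta <- vapply(fams, function(f) {
    tryCatch(stat_fn(data[data[[family]] != f, , drop = FALSE]),
             error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(theta)) {
    warn(sprintf("Statistic undefined on %d leave-one-out subset(s); skipped.",
                 sum(is.na(theta))))
    theta <- theta[!is.na(theta)]
  }
  m <- length(theta)
  sqrt((m - 1) / m * sum((theta - mean(theta))^2))
}

#' BLUP family breeding values
#'
#' Best linear unbiased prediction of the random family effect:
#' `BV_f = shrink * (family mean - grand mean)` with
#' `shrink = sigma2_f / (sigma2_f + sigma2_e / n_f)` for family size `n_f`.
#' Shrinkage lies in (0, 1), so a breeding value never exceeds the raw
#' family deviation.
#'
#' @param data Tibble with the trait and family label columns.
#' @param trait Trait column name.
#' @param vc Variance components for the trait (from
#'   [fit_univariate_reml()]); fitted on the fly when `NULL`.
#' @inheritParams fit_univariate_reml
#' @return Tibble with `family_id`, `n`, `bv`.
#' @export
breeding_values <- function(data, trait, vc = NULL, family = "family_id",
                            replication = "replication_id") {
  if (is.null(vc)) vc <- fit_univariate_reml(data, trait, family, replication)
  y <- as.numeric(data[[trait]])
  fam <- data[[family]]
  gm <- mean(y)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble(fam = fam, y = y), .data$fam),
    n = dplyr::n(), dev = mean(.data$y) - gm, .groups = "drop")
  shrink <- if (vc$sigma2_f <= 0) 0 else
    vc$sigma2_f / (vc$sigma2_f + vc$sigma2_e / agg$n)
  tibble(family_id = agg$fam, n = agg$n, bv = shrink * agg$dev)
}

#' Realized genetic gain from truncation selection on breeding values
#'
#' `dG_R = mean(BV of the top fraction of families, ranked by BV) -
#' mean(BV of all families)`. Selecting everybody yields zero gain; the gain
#' is non-increasing as the selected fraction grows.
#'
#' @param bv Breeding-value tibble with a `bv` column (or a trait-named
#'   `bv_<trait>` column selected via `trait`).
#' @param top_fraction Fraction of families retained (at least one family is
#'   always selected).
#' @param trait Optional trait name to pick `bv_<trait>` from a multi-trait
#'   table.
#' @return The realized gain, in trait units on the breeding-value scale.
#' @export
realized_gain <- function(bv, top_fraction, trait = NULL) {
  top_fraction <- check_fraction(top_fraction, "top_fraction")
  col <- if (!is.null(trait)) paste0("bv_", trait) else "bv"
  if (!col %in% names(bv)) stop_schema(sprintf("No column `%s`.", col))
  v <- sort(bv[[col]], decreasing = TRUE)
  n_top <- max(1L, ceiling(top_fraction * length(v)))
  mean(v[seq_len(n_top)]) - mean(v)
}

#' Multi-trait family selection by above-mean breeding values
#'
#' Keeps the families whose breeding value exceeds the across-family mean
#' for every listed trait (rule intersection). With no rules every family is
#' kept; an empty result is allowed.
#'
#' @param bv Multi-trait breeding-value tibble (columns `family_id`,
#'   `bv_<trait>`).
#' @param above_mean Character vector of trait names to require above-mean
#'   breeding values for.
#' @return The selected rows of `bv`.
#' @export
select_families <- function(bv, above_mean = character(0)) {
  keep <- rep(TRUE, nrow(bv))
  for (tr in above_mean) {
    col <- paste0("bv_", tr)
    if (!col %in% names(bv)) stop_schema(sprintf("No column `%s`.", col))
    keep <- keep & bv[[col]] > mean(bv[[col]])
  }
  bv[keep, , drop = FALSE]
}

#' Full genetic summary of a multi-trait half-sib trial
#'
#' Per-trait REML variance components and heritability, all pairwise genetic
#' and phenotypic correlations, BLUP family breeding values, and optional
#' delete-one-family jackknife standard errors for h2, r_g and r_p.
#'
#' @param data Tibble with trait columns and family/replication labels.
#' @param traits Trait column names.
#' @param k Heritability multiplier (default 2.5).
#' @param se Compute jackknife standard errors (slower; one REML refit set
#'   per family).
#' @inheritParams fit_univariate_reml
#' @return An object of class `nir_genetics`: `components` (per-trait
#'   tibble), `correlations` (per-pair tibble), `breeding_values` (wide
#'   per-family tibble with `bv_<trait>` and `rank_<trait>`), `k`.
#' @export
genetic_summary <- function(data, traits = c("anth", "flav", "nbi"), k = 2.5,
                            se = TRUE, family = "family_id",
                            replication = "replication_id") {
  vcs <- purrr::map(traits, ~fit_univariate_reml(data, .x, family, replication))
  names(vcs) <- traits
  components <- dplyr::bind_rows(vcs)
  components$h2 <- heritability(components, k)
  components$h2_se <- if (se) {
    vapply(traits, function(tr) jackknife_se(data, "h2", trait = tr, k = k,
                                             family = family,
                                             replication = replication),
           numeric(1))
  } else NA_real_

  pairs <- utils::combn(traits, 2L, simplify = FALSE)
  correlations <- dplyr::bind_rows(purrr::map(pairs, function(pr) {
    pc <- fit_pair_covariance(data, pr[1L], pr[2L], family, replication)
    tibble(
      trait_i = pr[1L], trait_j = pr[2L],
      cov_f = pc$cov_f, cov_e = pc$cov_e,
      r_g = genetic_correlation(pc, vcs[[pr[1L]]], vcs[[pr[2L]]]),
      r_g_se = if (se) jackknife_se(data, "r_g", trait_i = pr[1L],
                                    trait_j = pr[2L], family = family,
                                    replication = replication) else NA_real_,
      r_p = phenotypic_correlation(pc, vcs[[pr[1L]]], vcs[[pr[2L]]]),
      r_p_se = if (se) jackknife_se(data, "r_p", trait_i = pr[1L],
                                    trait_j = pr[2L], family = family,
                                    replication = replication) else NA_real_)
  }))

  bv_wide <- purrr::reduce(purrr::map(traits, function(tr) {
    b <- breeding_values(data, tr, vcs[[tr]], family, replication)
    out <- tibble(family_id = b$family_id)
    out[[paste0("bv_", tr)]] <- b$bv
    out[[paste0("rank_", tr)]] <- rank(-b$bv, ties.method = "min")
    out
  }), ~dplyr::inner_join(.x, .y, by = "family_id"))

  structure(list(components = components, correlations = correlations,
                 breeding_values = bv_wide, k = k,
                 n_trees = nrow(data)),
            class = "nir_genetics")
}

#' @export
print.nir_genetics <- function(x, ...) {
  cat(sprintf("<nir_genetics> %d traits, %d families, k = %g\n",
              nrow(x$components), x$components$n_families[1L], x$k))
  print(x$components[c("trait", "sigma2_f", "sigma2_e", "h2", "h2_se")])
  print(x$correlations[c("trait_i", "trait_j", "r_g", "r_p")])
  invisible(x)
}

#' @export
#' @method tidy nir_genetics
tidy.nir_genetics <- function(x, ...) x$components

#' @export
#' @method glance nir_genetics
glance.nir_genetics <- function(x, ...) {
  tibble(n_traits = nrow(x$components),
         n_families = x$components$n_families[1L],
         n_trees = x$n_trees, k = x$k,
         mean_h2 = mean(x$components$h2))
}
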