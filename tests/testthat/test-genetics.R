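# Closed-form ANOVA (expected mean squares) oracle for balanced designs:
# sigma2_f = (MS_family - MS_error) / n0, truncated at zero.
anova_oracle <- function(data, trait) {
  df <- data.frame(y = data[[trait]], fam = factor(data$family_id),
                   rep = factor(data$replication_id))
  tab <- anova(stats::aov(y ~ rep + fam, df))
  n0 <- nrow(df) / nlevels(df$fam)
  ms_f <- tab["fam", "Mean Sq"]
  ms_e <- tab["Residuals", "Mean Sq"]
  c(sigma2_f = max((ms_f - ms_e) / n0, 0), sigma2_e = ms_e)
}

sim_one_trait <- function(n_fam = 50, n_rep = 5, n_tree = 6, q = 0.312,
                          seed = 1) {
  simulate_traits(make_design(n_fam, n_rep, n_tree),
                  trait_params(mu = c(anth = 10, flav = 10, nbi = 10),
                               total_variance = c(anth = 1, flav = 1, nbi = 1),
                               family_ratio = c(anth = q, flav = q, nbi = q),
                               family_correlation = diag(3),
                               phenotypic_correlation = diag(3)),
                  seed = seed)
}

test_that("REML matches the balanced-design ANOVA oracle", {
  tt <- sim_one_trait(seed = 41)
  vc <- fit_univariate_reml(tt, "anth")
  oracle <- anova_oracle(tt, "anth")
  expect_equal(vc$sigma2_f, unname(oracle["sigma2_f"]), tolerance = 1e-4)
  expect_equal(vc$sigma2_e, unname(oracle["sigma2_e"]), tolerance = 1e-4)
})

test_that("a null trait gives a near-zero family variance", {
  tt <- sim_one_trait(q = 0, seed = 42)
  vc <- fit_univariate_reml(tt, "anth")
  expect_lt(vc$sigma2_f, 0.02)
  d <- tt[tt$family_id == 1, ]
  expect_error(fit_univariate_reml(d, "anth"),
               class = "nirherit_error_invalid_parameter")
})

test_that("pair covariance obeys the self-covariance identity and nulls", {
  tt <- sim_one_trait(seed = 43)
  tt$anth2 <- tt$anth
  pc <- fit_pair_covariance(tt, "anth", "anth2")
  vc <- fit_univariate_reml(tt, "anth")
  expect_equal(pc$cov_f, vc$sigma2_f, tolerance = 1e-6)
  expect_equal(pc$cov_e, vc$sigma2_e, tolerance = 1e-6)
  expect_equal(genetic_correlation(pc, vc, fit_univariate_reml(tt, "anth2")),
               1, tolerance = 1e-4)

  # independent traits: mean family covariance across replicates ~ 0
  covs <- vapply(1:20, function(s) {
    d <- sim_one_trait(n_fam = 30, n_rep = 2, n_tree = 3, seed = 100 + s)
    fit_pair_covariance(d, "anth", "flav")$cov_f
  }, numeric(1))
  expect_lt(abs(mean(covs)), 2 * sd(covs) / sqrt(20))
})

test_that("heritability and correlation formulas give the printed identities", {
  vc1 <- tibble::tibble(sigma2_f = 1, sigma2_e = 1.5)
  expect_equal(heritability(vc1, 2.5), 1.0)
  expect_equal(heritability(tibble::tibble(sigma2_f = 0, sigma2_e = 2)), 0)
  expect_equal(heritability(tibble::tibble(sigma2_f = 0.2, sigma2_e = 0.8)), 0.5)
  expect_error(heritability(tibble::tibble(sigma2_f = 0, sigma2_e = 0)),
               class = "nirherit_error_degenerate")

  pc <- tibble::tibble(cov_f = 0.3, cov_e = 0)
  expect_equal(genetic_correlation(pc, tibble::tibble(sigma2_f = 0.25),
                                   tibble::tibble(sigma2_f = 0.64)), 0.75)
  expect_equal(genetic_correlation(tibble::tibble(cov_f = 0),
                                   tibble::tibble(sigma2_f = 1),
                                   tibble::tibble(sigma2_f = 1)), 0)
  expect_error(genetic_correlation(pc, tibble::tibble(sigma2_f = 0),
                                   tibble::tibble(sigma2_f = 1)),
               class = "nirherit_error_degenerate")

  vci <- tibble::tibble(sigma2_f = 0.5, sigma2_e = 0.5)
  expect_equal(phenotypic_correlation(tibble::tibble(cov_f = 0.1, cov_e = 0.1),
                                      vci, vci), 0.2)
  expect_equal(phenotypic_correlation(tibble::tibble(cov_f = 0, cov_e = 0),
                                      vci, vci), 0)
})

test_that("heritability is invariant to rescaling the trait", {
  tt <- sim_one_trait(n_fam = 20, n_rep = 2, n_tree = 3, seed = 44)
  h1 <- heritability(fit_univariate_reml(tt, "anth"))
  tt$anth <- tt$anth * 37.5
  expect_equal(heritability(fit_univariate_reml(tt, "anth")), h1,
               tolerance = 1e-6)
})

test_that("jackknife SE behaves like the textbook estimator", {
  tt <- sim_one_trait(n_fam = 15, n_rep = 2, n_tree = 3, seed = 45)
  # jackknife of the mean on a balanced table equals SD(family means)/sqrt(F)
  se <- jackknife_se(tt, "mean", trait = "anth")
  fam_means <- tapply(tt$anth, tt$family_id, mean)
  expect_equal(se, sd(fam_means) / sqrt(length(fam_means)), tolerance = 1e-10)
  se_h2 <- jackknife_se(tt, "h2", trait = "anth")
  expect_gte(se_h2, 0)
  # constant statistic -> zero SE
  ttc <- tt; ttc$anth <- rep(3, nrow(tt))
  expect_equal(jackknife_se(ttc, "mean", trait = "anth"), 0)
})

test_that("breeding values are shrunken family deviations matching lme4 BLUPs", {
  tt <- sim_one_trait(seed = 46)
  vc <- fit_univariate_reml(tt, "anth")
  bv <- breeding_values(tt, "anth", vc)
  dev <- tapply(tt$anth, tt$family_id, mean) - mean(tt$anth)
  expect_true(all(abs(bv$bv) <= abs(dev) + 1e-12))
  expect_lt(abs(sum(bv$bv)), 1e-8)

  ref <- suppressMessages(lme4::lmer(
    anth ~ factor(replication_id) + (1 | family_id), tt, REML = TRUE))
  blup <- lme4::ranef(ref)$family_id[, 1]
  expect_equal(unname(bv$bv), unname(blup), tolerance = 1e-3)

  vc0 <- tibble::tibble(sigma2_f = 0, sigma2_e = 1)
  expect_true(all(breeding_values(tt, "anth", vc0)$bv == 0))
  vc_inf <- tibble::tibble(sigma2_f = 1, sigma2_e = 1e-12)
  expect_equal(breeding_values(tt, "anth", vc_inf)$bv, as.numeric(dev),
               tolerance = 1e-6)
})

test_that("realized gain is zero for select-all and non-increasing in fraction", {
  bv <- tibble::tibble(family_id = 1:10, bv = c(5, 3, 1, 0.5, 0, -0.5, -1, -2, -3, -3))
  expect_equal(realized_gain(bv, 1), 0)
  expect_equal(realized_gain(bv, 0.1), 5 - mean(bv$bv))
  fracs <- seq(0.1, 1, by = 0.1)
  gains <- vapply(fracs, function(f) realized_gain(bv, f), numeric(1))
  expect_true(all(diff(gains) <= 1e-12))
  expect_error(realized_gain(bv, 0), class = "nirherit_error_invalid_parameter")
})

test_that("family selection intersects above-mean rules", {
  bv <- tibble::tibble(family_id = 1:3, bv_anth = c(1, 1, -1),
                       bv_flav = c(1, -1, 1))
  expect_equal(select_families(bv, c("anth", "flav"))$family_id, 1)
  expect_equal(nrow(select_families(bv)), 3)
  s1 <- select_families(bv, "anth")
  s2 <- select_families(bv, c("anth", "flav"))
  expect_true(all(s2$family_id %in% s1$family_id))
})

test_that("genetic_summary assembles components, correlations and BVs", {
  tt <- sim_one_trait(n_fam = 12, n_rep = 2, n_tree = 3, seed = 47)
  gs <- genetic_summary(tt, k = 2.5, se = FALSE)
  expect_equal(nrow(gs$components), 3)
  expect_equal(nrow(gs$correlations), 3)
  expect_true(all(abs(gs$correlations$r_p) <= 1))
  expect_equal(nrow(gs$breeding_values), 12)
  expect_true(all(c("bv_anth", "rank_anth") %in% names(gs$breeding_values)))
  expect_equal(tidy(gs), gs$components)
  expect_equal(glance(gs)$n_families, 12)
})
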