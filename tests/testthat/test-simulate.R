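test_that("design table is balanced, unique and deterministic", {
  d <- make_design(50, 5, 6)
  expect_equal(nrow(d), 1500)
  expect_equal(nrow(make_design(1, 1, 1)), 1)
  expect_false(anyDuplicated(d$tree_id) > 0)
  cells <- dplyr::count(d, family_id, replication_id)
  expect_true(all(cells$n == 6))
  expect_identical(make_design(3, 2, 4), make_design(3, 2, 4))
  expect_error(make_design(0, 5, 6), class = "nirherit_error_invalid_parameter")
})

test_that("trait simulation honours the variance decomposition", {
  # Zero family covariance: family means vary only through residuals,
  # var(mean) ~ sigma2_e / (R*T) by the law of total variance.
  p0 <- trait_params()
  p0$cov_f <- p0$cov_f * 0
  p0$sigma2_f <- p0$sigma2_f * 0
  d <- make_design(400, 5, 6)
  tt <- simulate_traits(d, p0, seed = 7)
  fam_means <- dplyr::summarise(dplyr::group_by(tt, family_id),
                                m = mean(anth), .groups = "drop")
  expect_lt(abs(var(fam_means$m) - p0$sigma2_e[["anth"]] / 30),
            0.35 * p0$sigma2_e[["anth"]] / 30)

  # Monte-Carlo recovery of the family variance at inflated family count.
  pu <- trait_params(mu = c(anth = 10, flav = 10, nbi = 10),
                     total_variance = c(anth = 1, flav = 1, nbi = 1),
                     family_ratio = c(anth = 0.312, flav = 0.312, nbi = 0.312))
  du <- make_design(500, 1, 3)
  ttu <- simulate_traits(du, pu, seed = 8)
  fm <- dplyr::summarise(dplyr::group_by(ttu, family_id),
                         m = mean(anth), .groups = "drop")
  # var(family mean) = sigma2_f + sigma2_e/3
  expect_lt(abs((var(fm$m) - 0.688 / 3) - 0.312), 0.1 * 0.312)
})

test_that("trait simulation is seeded, truncated at zero, and emits chl", {
  d <- make_design(10, 2, 3)
  t1 <- simulate_traits(d, seed = 5)
  t2 <- simulate_traits(d, seed = 5)
  expect_identical(t1, t2)
  expect_false(identical(t1, simulate_traits(d, seed = 6)))
  expect_true(all(t1$anth >= 0 & t1$flav >= 0 & t1$nbi >= 0))
  expect_equal(t1$chl, t1$nbi * t1$flav)

  bad <- trait_params()
  bad$cov_e <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3, 3,
                      dimnames = dimnames(bad$cov_e))
  expect_error(simulate_traits(d, bad, seed = 1),
               class = "nirherit_error_invalid_parameter")
})

test_that("noiseless spectra equal the additive mixing model exactly", {
  par <- spectra_params(peaks = list(
    anth = list(centers = 1400, width = 50, amplitudes = 0.7)),
    scatter_sd = 0, noise_sd = 0, n_scans = 1)
  tr <- tibble::tibble(tree_id = "a", anth = 1)
  sp <- simulate_spectra(tr, par, seed = 1)
  sm <- spectra_matrix(sp)
  wl <- sm$wavelengths
  expected <- 0.7 * exp(-(wl - 1400)^2 / (2 * 50^2)) + 0.3 + 1e-4 * (wl - 1100)
  expect_equal(drop(sm$values), expected, tolerance = 1e-12)
  expect_equal(ncol(spectra_matrix(simulate_spectra(
    tibble::tibble(tree_id = "a", anth = 1, flav = 1, chl = 1),
    spectra_params(), seed = 1))$values), 234)
})

test_that("spectra generation is linear in concentrations when noiseless", {
  par <- spectra_params(scatter_sd = 0, noise_sd = 0, n_scans = 1)
  t1 <- tibble::tibble(tree_id = "a", anth = 0.4, flav = 0.9, chl = 0.3)
  t2 <- tibble::tibble(tree_id = "a", anth = 0.2, flav = 0.1, chl = 0.5)
  t12 <- tibble::tibble(tree_id = "a", anth = 0.6, flav = 1.0, chl = 0.8)
  s1 <- spectra_matrix(simulate_spectra(t1, par, 1))$values
  s2 <- spectra_matrix(simulate_spectra(t2, par, 1))$values
  s12 <- spectra_matrix(simulate_spectra(t12, par, 1))$values
  wl <- spectra_matrix(simulate_spectra(t1, par, 1))$wavelengths
  baseline <- 0.3 + 1e-4 * (wl - 1100)
  expect_equal(drop(s12), drop(s1) + drop(s2) - baseline, tolerance = 1e-10)
})

test_that("scan averaging reduces noise variance as 1/n_scans", {
  base <- list(peaks = list(anth = list(centers = 1400, width = 50,
                                        amplitudes = 0)),
               scatter_sd = 0, noise_sd = 0.1)
  tr <- tibble::tibble(tree_id = sprintf("t%d", 1:400), anth = 0)
  par1 <- do.call(spectra_params, c(base, list(baseline_coeffs = c(0, 0), n_scans = 1)))
  par3 <- do.call(spectra_params, c(base, list(baseline_coeffs = c(0, 0), n_scans = 3)))
  v1 <- var(as.vector(spectra_matrix(simulate_spectra(tr, par1, 3))$values))
  v3 <- var(as.vector(spectra_matrix(simulate_spectra(tr, par3, 4))$values))
  expect_equal(v3 / v1, 1 / 3, tolerance = 0.05)
})

test_that("spectra are a deterministic function of traits, params and seed", {
  tr <- simulate_traits(make_design(4, 2, 2), seed = 3)
  expect_identical(simulate_spectra(tr, seed = 9), simulate_spectra(tr, seed = 9))
  expect_error(simulate_spectra(tr[setdiff(names(tr), "chl")],
                                spectra_params(), seed = 1),
               class = "nirherit_error_schema")
})

test_that("measured-subset mask is stratified, exact and seed-sensitive", {
  d <- make_design(50, 5, 6)
  m <- subsample_measured(d, 500, seed = 2)
  expect_equal(sum(m), 500)
  expect_true(all(table(d$family_id[m]) >= 1))
  expect_true(all(subsample_measured(d, nrow(d), seed = 1)))
  expect_false(identical(subsample_measured(d, 500, seed = 1),
                         subsample_measured(d, 500, seed = 2)))
  expect_error(subsample_measured(d, nrow(d) + 1, seed = 1),
               class = "nirherit_error_invalid_parameter")
})
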