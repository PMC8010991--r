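# Shared small high-SNR fixture for harness tests.
eval_fixture <- function(seed = 20, n = 100, p = 40) {
  fx <- planted_fixture(n = n, p = p, bands = c(8, 20, 33),
                        coefs = c(2, -1, 1.5), noise_sd = 0.05, seed = seed)
  sp <- as_spectra(fx$X)
  traits <- tibble::tibble(tree_id = sp$tree_id, resp = fx$y)
  list(spectra = sp, traits = traits)
}

test_that("the repeated-split harness is complete, disjoint and reproducible", {
  fx <- eval_fixture()
  ev <- evaluate_pipeline(fx$spectra, fx$traits, "resp", n_rep = 12, seed = 3)
  expect_equal(nrow(ev$records), 12)
  expect_false(any(ev$records$failed))

  ev2 <- evaluate_pipeline(fx$spectra, fx$traits, "resp", n_rep = 12, seed = 3)
  expect_identical(ev$records, ev2$records)

  # splits: disjoint and exhaustive in every repetition (reconstruct them
  # from the derived per-repetition seed)
  n <- nrow(fx$spectra)
  n_cal <- round(0.8 * n)
  for (r in c(1, 5, 12)) {
    set.seed(nirherit:::derive_seed(3, r, 0L))
    idx_cal <- sort(sample.int(n, n_cal))
    expect_length(union(idx_cal, setdiff(seq_len(n), idx_cal)), n)
    expect_equal(ev$records$split_hash[r],
                 sum(idx_cal * seq_along(idx_cal)) %% 2147483647)
  }
})

test_that("a high-SNR fixture is predicted accurately with the full spectrum", {
  fx <- eval_fixture()
  ev <- evaluate_pipeline(fx$spectra, fx$traits, "resp", n_rep = 10, seed = 4)
  expect_gte(mean(ev$records$r2_val), 0.9)
})

test_that("summaries recompute from the records", {
  fx <- eval_fixture()
  ev <- evaluate_pipeline(fx$spectra, fx$traits, "resp", n_rep = 10, seed = 5)
  s <- summarise_evaluation(ev)
  expect_setequal(s$statistic, c("r2_cal", "rmse_cal", "r2_val", "rmse_val"))
  row <- s[s$statistic == "r2_val", ]
  expect_equal(row$mean, mean(ev$records$r2_val), tolerance = 1e-12)
  expect_true(row$p2.5 <= stats::median(ev$records$r2_val) &&
                stats::median(ev$records$r2_val) <= row$p97.5)
  expect_true(all(s$min <= s$mean & s$mean <= s$max))
})

test_that("selector runs inside the loop and excluded bands carry no signal", {
  fx <- eval_fixture()
  ev <- evaluate_pipeline(fx$spectra, fx$traits, "resp", selector = "smc",
                          n_rep = 6, seed = 6)
  never <- !apply(ev$stability, 2, any)
  expect_gt(sum(never), 0)
  # zeroing never-selected bands in the validation rows leaves every
  # validation statistic untouched: no signal leaks through excluded bands
  sm <- nirherit:::spectra_matrix(fx$spectra)
  Xz <- sm$values
  Xz[, never] <- 0
  n <- nrow(Xz)
  n_cal <- round(0.8 * n)
  y <- fx$traits$resp
  for (r in seq_len(6)) {
    set.seed(nirherit:::derive_seed(6, r, 0L))
    idx_cal <- sort(sample.int(n, n_cal))
    idx_val <- setdiff(seq_len(n), idx_cal)
    m <- ev$models[[r]]
    pred <- drop(sweep(Xz[idx_val, m$mask, drop = FALSE], 2, m$x_mean) %*%
                   m$coefficients) + m$y_mean
    expect_equal(fit_stats(y[idx_val], pred)$r_squared,
                 ev$records$r2_val[r], tolerance = 1e-10)
  }
})

test_that("the grid is paired across cells and ranks sensibly", {
  fx <- eval_fixture()
  g1 <- grid_search(fx$spectra, fx$traits, "resp", methods = "raw",
                    selectors = "none", n_rep = 6, seed = 7)
  expect_equal(g1$best, list(method = "raw", selector = "none"))

  # a pure-offset signal: y follows the per-sample offset, which a 2nd
  # derivative annihilates -> d2 must rank below raw
  set.seed(30)
  off <- rnorm(80)
  X <- matrix(rnorm(80 * 40, 0, 0.02), 80, 40) + off
  sp <- as_spectra(X)
  traits <- tibble::tibble(tree_id = sp$tree_id, resp = off + rnorm(80, 0, 0.01))
  g2 <- grid_search(sp, traits, "resp", methods = c("raw", "d2"),
                    selectors = "none", n_rep = 6, seed = 8)
  expect_equal(g2$best$method, "raw")
  r2 <- g2$summary$mean_r2_val
  expect_gt(r2[g2$summary$method == "raw"], r2[g2$summary$method == "d2"])

  # shared splits across cells
  recs <- purrr::map(g2$evaluations, ~.x$records$split_hash)
  expect_identical(recs[[1]], recs[[2]])
})

test_that("paired grids show no systematic cell difference on pure noise", {
  set.seed(31)
  X <- matrix(rnorm(60 * 30), 60, 30)
  sp <- as_spectra(X)
  traits <- tibble::tibble(tree_id = sp$tree_id, resp = rnorm(60))
  g <- grid_search(sp, traits, "resp", methods = c("raw", "snv"),
                   selectors = "none", n_rep = 10, seed = 9)
  d <- g$evaluations[[1]]$records$r2_val - g$evaluations[[2]]$records$r2_val
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 0.05)
})

test_that("ensemble prediction averages models and carries uncertainty", {
  m1 <- list(mask = rep(TRUE, 3), x_mean = rep(0, 3), y_mean = 1,
             coefficients = rep(0, 3), ncomp = 1)
  m2 <- m1; m2$y_mean <- 3
  ev <- structure(list(models = list(m1, m2), wavelengths = c(1100, 1106, 1112),
                       config = list(method = "raw", window = 15, polyorder = 2)),
                  class = "nir_evaluation")
  sp <- as_spectra(matrix(0, 2, 3))
  out <- ensemble_predict(ev, sp)
  expect_equal(out$pred, c(2, 2))
  expect_equal(out$pred_sd, c(sqrt(2), sqrt(2)))
  evs <- ev; evs$models <- list(m1, m1)
  expect_equal(ensemble_predict(evs, sp)$pred_sd, c(0, 0))

  # end-to-end: ensemble mean tracks the measured values on a high-SNR fixture
  fx <- eval_fixture()
  ev2 <- evaluate_pipeline(fx$spectra, fx$traits, "resp", n_rep = 8, seed = 10)
  pred <- ensemble_predict(ev2, fx$spectra)
  expect_gte(fit_stats(fx$traits$resp, pred$pred)$r_squared, 0.9)
})

test_that("residual tables subtract predictions from measurements", {
  rt <- residual_table(c(1, 2), c(0.7, 2.5), c(0.1, 0.2))
  expect_equal(rt$residual, c(0.3, -0.5))
  expect_equal(residual_table(c(1, 2), c(1, 2))$residual, c(0, 0))
  fx <- eval_fixture()
  ev <- evaluate_pipeline(fx$spectra, fx$traits, "resp", n_rep = 6, seed = 11)
  pred <- ensemble_predict(ev, fx$spectra)
  rt2 <- residual_table(fx$traits$resp, pred$pred, pred$pred_sd)
  expect_lt(abs(mean(rt2$residual)), 0.05)
})
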