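test_that("a single latent factor is captured by one component", {
  # orthogonal centered bands: y proportional to one band is one latent factor
  set.seed(1)
  M <- scale(matrix(rnorm(20 * 10), 20, 10), scale = FALSE)
  X <- qr.Q(qr(M))
  y <- 2 * X[, 7]
  fit <- fit_plsr(X, y, 1)
  expect_gt(fit_stats(y, predict(fit, X))$r_squared, 1 - 1e-8)
})

test_that("full-rank PLSR matches the least-squares oracle", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(12 * 4), 12, 4)
    y <- rnorm(12)
    fit <- fit_plsr(X, y, 4)
    ols <- stats::lm.fit(cbind(1, X), y)
    expect_lt(max(abs(predict(fit, X) - ols$fitted.values)), 1e-6)
  }
})

test_that("collinear bands do not break the decomposition", {
  set.seed(2)
  X <- matrix(rnorm(15 * 6), 15, 6)
  X[, 6] <- X[, 5]
  y <- rnorm(15)
  fit <- suppressWarnings(fit_plsr(X, y, 5))
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all(is.finite(predict(fit, X))))
})

test_that("prediction is the centered linear map and matches score space", {
  set.seed(3)
  X <- matrix(rnorm(25 * 12), 25, 12)
  y <- drop(X %*% rnorm(12)) + rnorm(25, 0, 0.2)
  fit <- fit_plsr(X, y, 4)
  expect_equal(predict(fit, X), drop(sweep(X, 2, fit$x_mean) %*%
                                       fit$coefficients) + fit$y_mean)
  expect_equal(drop(predict(fit, matrix(fit$x_mean, 1))), fit$y_mean)
  # two-path equivalence: scores T q vs regression vector
  score_path <- drop(fit$scores %*% fit$y_loadings) + fit$y_mean
  expect_lt(max(abs(score_path - predict(fit, X))), 1e-8)
  expect_error(predict(fit, X[, 1:5]), class = "nirherit_error_schema")
})

test_that("scores are orthogonal and training RMSE decreases with components", {
  set.seed(4)
  X <- matrix(rnorm(30 * 20), 30, 20)
  y <- rnorm(30)
  fit <- fit_plsr(X, y, 8)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  rmse_k <- vapply(1:8, function(k) fit_stats(y, predict(fit, X, k))$rmse,
                   numeric(1))
  expect_true(all(diff(rmse_k) <= 1e-12))
})

test_that("row permutation only permutes scores", {
  set.seed(5)
  X <- matrix(rnorm(18 * 9), 18, 9)
  y <- rnorm(18)
  perm <- sample(18)
  f1 <- fit_plsr(X, y, 3)
  f2 <- fit_plsr(X[perm, ], y[perm], 3)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$scores[perm, ], f2$scores, tolerance = 1e-10)
})

test_that("degenerate inputs raise classed errors", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_plsr(X, rep(1, 10), 1), class = "nirherit_error_degenerate")
  expect_error(fit_plsr(X, rnorm(10), 3),
               class = "nirherit_error_invalid_parameter")
  expect_error(fit_plsr(X, rnorm(9), 1), class = "nirherit_error_schema")
})

test_that("fit_stats reproduces hand-computed values and never clamps", {
  expect_equal(as.numeric(fit_stats(c(0, 1, 2), c(0, 1, 2))), c(1, 0))
  y <- c(1, 2, 3, 4)
  expect_equal(fit_stats(y, rep(mean(y), 4))$r_squared, 0)
  expect_equal(fit_stats(c(0, 1, 2), c(0, 1, 5))$rmse, sqrt(3))
  expect_lt(fit_stats(c(0, 1, 2), c(5, 5, 5))$r_squared, 0)
  expect_error(fit_stats(rep(1, 3), rnorm(3)), class = "nirherit_error_degenerate")
})

test_that("leave-one-out curve matches a brute-force refit loop", {
  set.seed(6)
  X <- matrix(rnorm(6 * 5), 6, 5)
  y <- rnorm(6)
  res <- loo_select_ncomp(X, y, max_ncomp = 3)
  brute <- vapply(0:3, function(k) {
    e <- vapply(1:6, function(i) {
      if (k == 0) return(y[i] - mean(y[-i]))
      f <- fit_plsr(X[-i, ], y[-i], k)
      y[i] - drop(predict(f, X[i, , drop = FALSE]))
    }, numeric(1))
    sqrt(mean(e^2))
  }, numeric(1))
  expect_equal(res$curve$rmsecv, brute, tolerance = 1e-10)
  # zero-component entry has a closed form: pop-SD * n/(n-1)
  expect_equal(res$curve$rmsecv[1],
               sqrt(mean((y - mean(y))^2)) * 6 / 5, tolerance = 1e-12)
})

test_that("component selection finds low-rank structure parsimoniously", {
  set.seed(7)
  n <- 40; p <- 30
  scores <- matrix(rnorm(n * 2), n, 2)
  X <- scores %*% matrix(rnorm(2 * p), 2, p) + matrix(rnorm(n * p, 0, 1e-6), n, p)
  y <- drop(scores %*% c(1, -2))
  res <- loo_select_ncomp(X, y, max_ncomp = 8)
  expect_lte(res$best, 3)
  expect_warning(loo_select_ncomp(X[1:5, ], y[1:5], max_ncomp = 10),
                 "clipped")
})

test_that("the kernel coefficient path equals the NIPALS path", {
  set.seed(8)
  X <- matrix(rnorm(30 * 50), 30, 50)
  y <- rnorm(30)
  fit <- fit_plsr(X, y, 8)
  cs <- nirherit:::center_stats(nirherit:::cross_stats(X, y))
  B <- nirherit:::pls_coef_path(cs$S, cs$s, 8)
  expect_lt(max(abs(B - fit$coef_path)), 1e-8)
})
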