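# Partial least squares regression: NIPALS fit, prediction, leave-one-out
# component selection and fit statistics.
#
# Cross-validation loops use a crossproduct ("kernel") formulation of PLS1
# operating on X'X and X'y with rank-one downdates per held-out sample, which
# gives coefficient paths identical to NIPALS (asserted in the test suite)
# at a fraction of the cost when n is large.

# ---- crossproduct engine ----------------------------------------------------

cross_stats <- function(X, y) {
  list(Sxx = crossprod(X), sxy = drop(crossprod(X, y)),
       sx = colSums(X), sy = sum(y), n = nrow(X))
}

center_stats <- function(st) {
  mx <- st$sx / st$n
  my <- st$sy / st$n
  list(S = st$Sxx - tcrossprod(st$sx) / st$n,
       s = st$sxy - st$sx * my,
       mx = mx, my = my, n = st$n)
}

stats_drop_rows <- function(st, Xr, yr) {
  if (is.null(dim(Xr))) Xr <- matrix(Xr, nrow = 1L)
  list(Sxx = st$Sxx - crossprod(Xr),
       sxy = st$sxy - drop(crossprod(Xr, yr)),
       sx = st$sx - colSums(Xr),
       sy = st$sy - sum(yr),
       n = st$n - length(yr))
}

# Coefficient paths B[, k] for k = 1..ncomp from centered crossproducts
# (S = Xc'Xc, s = Xc'y). If the signal exhausts before ncomp components the
# remaining columns repeat the last valid path.
pls_coef_path <- function(S, s, ncomp) {
  p <- length(s)
  B <- matrix(0, p, ncomp)
  Rm <- matrix(0, p, ncomp)
  Pm <- matrix(0, p, ncomp)
  b <- numeric(p)
  a <- s
  s0 <- s
  scale0 <- sum(s0^2)
  if (scale0 < .Machine$double.xmin) return(B)
  for (h in seq_len(ncomp)) {
    nw2 <- sum(a^2)
    if (nw2 <= 1e-24 * scale0) {
      if (h <= ncomp) B[, h:ncomp] <- b
      break
    }
    w <- a / sqrt(nw2)
    r <- w
    if (h > 1L) {
      r <- r - Rm[, 1:(h - 1L), drop = FALSE] %*%
        crossprod(Pm[, 1:(h - 1L), drop = FALSE], w)
    }
    Sr <- S %*% r
    tt <- drop(crossprod(r, Sr))
    if (!is.finite(tt) || tt <= 1e-24 * sum(diag(S))) {
      B[, h:ncomp] <- b
      break
    }
    Rm[, h] <- r
    Pm[, h] <- Sr / tt
    q <- drop(crossprod(r, s0)) / tt
    b <- b + q * r
    B[, h] <- b
    a <- a - Pm[, h] * (q * tt)
  }
  B
}

# ---- user-facing model ------------------------------------------------------

#' Fit a PLS1 regression by NIPALS
#'
#' Mean-centers `x` and `y` (no autoscaling: NIR band variance is
#' informative) and extracts `ncomp` latent components by the NIPALS
#' iteration, deflating X at each step. Scores are mutually orthogonal; the
#' accumulated regression vector reproduces the component-wise predictions.
#' Collinear or duplicated bands are handled without failure; if the signal
#' is exhausted before `ncomp` components the model is truncated with a
#' warning.
#'
#' @param x Spectra as a wide tibble or numeric matrix (samples x bands).
#' @param y Numeric response, one value per sample.
#' @param ncomp Number of latent components.
#' @return An object of class `nir_plsr` with elements `x_mean`, `y_mean`,
#'   `weights`, `loadings`, `y_loadings`, `scores`, `coef_path` (p x ncomp),
#'   `coefficients` (final column), `ncomp`, `wavelengths`, `dims`.
#' @export
fit_plsr <- function(x, y, ncomp) {
  sm <- spectra_matrix(x)
  X <- sm$values
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop_schema("`y` length must match the number of spectra.")
  if (anyNA(X) || anyNA(y)) stop_invalid("Missing values are not allowed.")
  if (n < 2L) stop_invalid("Need at least 2 samples.")
  ncomp <- check_count(ncomp, "ncomp")
  if (ncomp > min(n - 1L, p)) {
    stop_invalid(sprintf("`ncomp` (%d) exceeds min(n - 1, p) = %d.",
                         ncomp, min(n - 1L, p)))
  }
  if (sd(y) == 0) stop_degenerate("`y` has zero variance.")

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  qv <- numeric(ncomp)
  used <- 0L
  Xd <- Xc
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(yc^2)))) break
    w <- w / nw
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    if (tt < .Machine$double.eps * n) break
    p_ <- drop(crossprod(Xd, t_)) / tt
    q_ <- sum(yc * t_) / tt
    Xd <- Xd - tcrossprod(t_, p_)
    W[, h] <- w; P[, h] <- p_; Tm[, h] <- t_; qv[h] <- q_
    used <- h
  }
  if (used < ncomp) {
    warn(sprintf("Signal exhausted after %d of %d requested components.",
                 used, ncomp))
    W <- W[, seq_len(used), drop = FALSE]
    P <- P[, seq_len(used), drop = FALSE]
    Tm <- Tm[, seq_len(used), drop = FALSE]
    qv <- qv[seq_len(used)]
    ncomp <- used
  }
  # R = W (P'W)^-1; coefficient path B_k = sum_{j<=k} r_j q_j
  coef_path <- if (ncomp > 0L) {
    Rm <- W %*% backsolve(crossprod(P, W), diag(ncomp), upper.tri = TRUE)
    apply(sweep(Rm, 2L, qv, `*`), 1L, cumsum)
  } else numeric(0)
  coef_path <- if (ncomp > 1L) t(coef_path) else matrix(coef_path, ncol = max(ncomp, 1L))

  structure(list(
    x_mean = x_mean, y_mean = y_mean,
    weights = W, loadings = P, y_loadings = qv, scores = Tm,
    coef_path = coef_path,
    coefficients = if (ncomp > 0L) coef_path[, ncomp] else rep(0, p),
    ncomp = ncomp, wavelengths = sm$wavelengths,
    dims = c(n = n, p = p)
  ), class = "nir_plsr")
}

#' Predict from a fitted PLSR model
#'
#' `yhat = y_mean + (x_new - x_mean) . b`, optionally with the coefficient
#' path truncated to fewer components.
#'
#' @param object A `nir_plsr` model.
#' @param newdata Spectra tibble or matrix with the training band count.
#' @param ncomp Components to use (default: all fitted).
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.nir_plsr <- function(object, newdata, ncomp = NULL, ...) {
  sm <- spectra_matrix(newdata)
  if (ncol(sm$values) != object$dims[["p"]]) {
    stop_schema(sprintf("New spectra have %d bands; model was trained on %d.",
                        ncol(sm$values), object$dims[["p"]]))
  }
  ncomp <- ncomp %||% object$ncomp
  if (ncomp > object$ncomp) stop_invalid("`ncomp` exceeds the fitted components.")
  b <- if (ncomp == 0L) rep(0, object$dims[["p"]]) else object$coef_path[, ncomp]
  drop(sweep(sm$values, 2L, object$x_mean) %*% b) + object$y_mean
}

#' @export
print.nir_plsr <- function(x, ...) {
  cat(sprintf("<nir_plsr> %d components, trained on %d samples x %d bands\n",
              x$ncomp, x$dims[["n"]], x$dims[["p"]]))
  invisible(x)
}

#' Calibration/validation fit statistics
#'
#' `r_squared = 1 - SSres/SStot` (about the mean of `y`; may be negative on
#' validation data and is never clamped) and `rmse = sqrt(mean((y - yhat)^2))`.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return A one-row tibble with `r_squared` and `rmse`.
#' @export
fit_stats <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_schema("`y` and `yhat` lengths differ.")
  if (length(y) < 2L) stop_invalid("Need at least 2 observations.")
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) stop_degenerate("`y` has zero variance; R^2 undefined.")
  ssres <- sum((y - yhat)^2)
  tibble(r_squared = 1 - ssres / sstot, rmse = sqrt(mean((y - yhat)^2)))
}

#' Leave-one-out selection of the number of PLS components
#'
#' Computes RMSECV for 0..`max_ncomp` components by refitting the model with
#' each sample left out in turn (0 components = intercept-only mean
#' prediction). The chosen size is the smallest k whose RMSECV is within
#' `tol` (relative) of the minimum -- a parsimony rule that avoids chasing
#' noise-level improvements with extra components.
#'
#' @param x Spectra tibble or matrix.
#' @param y Numeric response.
#' @param max_ncomp Largest component count to consider (clipped with a
#'   warning to n - 2 when the sample is small).
#' @param tol Relative tolerance of the parsimony rule (default 0.02).
#' @return A list with `best` (integer) and `curve`, a tibble of `ncomp` and
#'   `rmsecv` from 0 upward.
#' @export
loo_select_ncomp <- function(x, y, max_ncomp = 20, tol = 0.02) {
  sm <- spectra_matrix(x)
  X <- sm$values
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop_invalid("Leave-one-out selection needs at least 3 samples.")
  max_ncomp <- check_count(max_ncomp, "max_ncomp")
  cap <- min(n - 2L, ncol(X))
  if (max_ncomp > cap) {
    warn(sprintf("`max_ncomp` clipped from %d to %d (n = %d, p = %d).",
                 max_ncomp, cap, n, ncol(X)))
    max_ncomp <- cap
  }
  rmsecv <- drop(.loo_rmsecv_cpp(X, as.numeric(y), as.integer(max_ncomp)))
  curve <- tibble(ncomp = 0:max_ncomp, rmsecv = rmsecv)
  best <- min(which(rmsecv <= (1 + tol) * min(rmsecv))) - 1L
  list(best = as.integer(best), curve = curve)
}

# k-fold CV RMSE on a band subset, reusing per-fold raw crossproducts.
# `fold_stats` comes from make_fold_stats(); `idx` indexes bands.
make_fold_stats <- function(X, y, n_folds, seed) {
  n <- nrow(X)
  n_folds <- min(n_folds, n)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  full <- cross_stats(X, y)
  lapply(seq_len(n_folds), function(f) {
    out_rows <- which(fold == f)
    list(held_in = stats_drop_rows(full, X[out_rows, , drop = FALSE], y[out_rows]),
         rows = out_rows)
  })
}

cv_rmse_subset <- function(fold_stats, X, y, idx, ncomp) {
  err2 <- 0
  n <- 0L
  for (fs in fold_stats) {
    st <- fs$held_in
    sti <- list(Sxx = st$Sxx[idx, idx, drop = FALSE], sxy = st$sxy[idx],
                sx = st$sx[idx], sy = st$sy, n = st$n)
    cs <- center_stats(sti)
    k <- min(ncomp, sti$n - 1L, length(idx))
    B <- pls_coef_path(cs$S, cs$s, k)
    Xo <- X[fs$rows, idx, drop = FALSE]
    pred <- cs$my + drop(sweep(Xo, 2L, cs$mx) %*% B[, k])
    err2 <- err2 + sum((y[fs$rows] - pred)^2)
    n <- n + length(fs$rows)
  }
  sqrt(err2 / n)
}

# ---- broom-style methods ----------------------------------------------------

#' @export
#' @method tidy nir_plsr
tidy.nir_plsr <- function(x, ...) {
  tibble(wavelength = x$wavelengths,
         term = paste0("w", format(x$wavelengths, trim = TRUE)),
         estimate = x$coefficients)
}

#' @export
#' @method glance nir_plsr
glance.nir_plsr <- function(x, ...) {
  tibble(n = x$dims[["n"]], p = x$dims[["p"]], ncomp = x$ncomp)
}
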