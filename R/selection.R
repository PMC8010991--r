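# Wavelength selection: significance multivariate correlation (sMC),
# iterative predictor weighting (IPW), regularized backward elimination (REP)
# and a genetic algorithm (GA), all behind one SelectionResult contract.

new_selection <- function(method, scores, selected, threshold, wavelengths,
                          provenance) {
  if (!any(selected)) {
    # The contract guarantees at least one band; fall back to the top score.
    selected[which.max(scores)] <- TRUE
    provenance$forced_top_band <- TRUE
  }
  structure(list(method = method, scores = scores, selected = selected,
                 threshold = threshold, wavelengths = wavelengths,
                 provenance = provenance),
            class = "nir_selection")
}

#' @export
print.nir_selection <- function(x, ...) {
  cat(sprintf("<nir_selection> method %s: %d / %d bands selected (threshold %.4g)\n",
              x$method, sum(x$selected), length(x$selected), x$threshold))
  invisible(x)
}

#' @export
#' @method tidy nir_selection
tidy.nir_selection <- function(x, ...) {
  tibble(wavelength = x$wavelengths, score = x$scores, selected = x$selected)
}

#' Registered selector names
#' @return Character vector: `none, smc, ipw, rep, ga`.
#' @export
selector_methods <- function() c("none", "smc", "ipw", "rep", "ga")

#' Run a named wavelength selector
#'
#' Dispatcher used by the evaluation harness; `method = "none"` selects every
#' band.
#'
#' @param x Spectra tibble or matrix.
#' @param y Response.
#' @param method One of [selector_methods()].
#' @param seed Integer seed for the stochastic selectors (GA, CV folds).
#' @param ... Passed to the specific selector.
#' @return A `nir_selection` object.
#' @export
run_selector <- function(x, y, method, seed = 1, ...) {
  if (!method %in% selector_methods()) {
    stop_invalid(sprintf("Unknown selector `%s`.", method))
  }
  sm <- spectra_matrix(x)
  switch(method,
    none = new_selection("none", scores = rep(1, ncol(sm$values)),
                         selected = rep(TRUE, ncol(sm$values)),
                         threshold = 0, wavelengths = sm$wavelengths,
                         provenance = list()),
    smc = select_smc(x, y, ...),
    ipw = select_ipw(x, y, ...),
    rep = select_rep(x, y, seed = seed, ...),
    ga = select_ga(x, y, seed = seed, ...)
  )
}

#' Significance multivariate correlation (sMC) selection
#'
#' Projects each (centered) band onto the PLSR prediction direction
#' `u = Xb` and forms an F-like statistic per band j:
#' `SSreg_j = (x_j' u_(-j))^2 / ||u_(-j)||^2`,
#' `SSres_j = ||x_j||^2 - SSreg_j`,
#' `sMC_j = SSreg_j / (SSres_j / (n - 2))`, where `u_(-j) = u - x_j b_j` is
#' the prediction direction with band j's own additive contribution removed.
#' Scoring against `u_(-j)` is what makes the F(1, n - 2) reference
#' distribution calibrated: under a null band the direction it is scored
#' against is independent of it, so the selected fraction matches `alpha`,
#' whereas scoring against `u` itself lets every band's chance contribution
#' to `u` inflate its own statistic. When a band essentially *is* the model
#' direction (`u_(-j)` has negligible norm) the unadjusted projection is
#' used, preserving power on dominant single-band signals. Bands exceeding
#' the upper-alpha quantile of F(1, n - 2) are selected.
#'
#' @param x Spectra tibble or matrix.
#' @param y Response.
#' @param max_ncomp Cap on components for the underlying PLSR fit.
#' @param alpha Significance level of the F cutoff (default 0.05).
#' @param ncomp Explicit component count; default `NULL` picks it by
#'   leave-one-out cross-validation (capped at `max_ncomp`).
#' @return A `nir_selection` object.
#' @export
select_smc <- function(x, y, max_ncomp = 10, alpha = 0.05, ncomp = NULL) {
  sm <- spectra_matrix(x)
  X <- sm$values
  y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(ncomp)) ncomp <- max(1L, loo_select_ncomp(x, y, max_ncomp)$best)
  fit <- fit_plsr(X, y, ncomp)
  Xc <- sweep(X, 2L, colMeans(X))
  b <- fit$coefficients
  u <- drop(Xc %*% b)
  uu <- sum(u^2)
  if (uu < .Machine$double.eps) {
    stop_degenerate("PLSR prediction direction has zero norm; sMC undefined.")
  }
  xu <- drop(crossprod(Xc, u))
  xx <- colSums(Xc^2)
  xu_adj <- xu - xx * b
  uu_adj <- pmax(uu - 2 * b * xu + b^2 * xx, 0)
  ssreg <- ifelse(uu_adj > 1e-12 * uu, xu_adj^2 / uu_adj, xu^2 / uu)
  sstot <- xx
  ssres <- pmax(sstot - ssreg, 1e-12 * pmax(sstot, .Machine$double.xmin))
  smc <- ssreg / (ssres / (n - 2L))
  smc[sstot == 0] <- 0
  cutoff <- qf(1 - alpha, 1, n - 2L)
  new_selection("smc", scores = smc, selected = smc > cutoff,
                threshold = cutoff, wavelengths = sm$wavelengths,
                provenance = list(alpha = alpha, ncomp = ncomp))
}

#' Iterative predictor weighting (IPW) selection
#'
#' Repeatedly refits PLSR on importance-weighted bands. The importance of
#' band j at each pass is `|b_j| * sd(x_j w_j)` (coefficient times the SD of
#' the weighted band), normalized to mean 1; running weights are multiplied
#' by it, concentrating mass on informative bands. Iteration stops at
#' `max_iter` or when the selected set stops changing. Bands whose final
#' weight exceeds `keep_threshold` times the maximum weight are selected.
#'
#' @param x Spectra tibble or matrix.
#' @param y Response.
#' @param max_iter Maximum weighting passes.
#' @param keep_threshold Fraction of the maximum weight a band must reach.
#' @param max_ncomp Components for the internal PLSR fits.
#' @return A `nir_selection` object.
#' @export
select_ipw <- function(x, y, max_iter = 10, keep_threshold = 0.1,
                       max_ncomp = 10) {
  max_iter <- check_count(max_iter, "max_iter")
  keep_threshold <- check_fraction(keep_threshold, "keep_threshold")
  sm <- spectra_matrix(x)
  X <- sm$values
  y <- as.numeric(y)
  p <- ncol(X)
  ncomp <- min(max_ncomp, nrow(X) - 1L, p)
  v <- rep(1, p)
  selected_prev <- NULL
  for (it in seq_len(max_iter)) {
    Xw <- sweep(X, 2L, v, `*`)
    fit <- fit_plsr(Xw, y, ncomp)
    z <- abs(fit$coefficients) * apply(Xw, 2L, sd)
    if (mean(z) < .Machine$double.xmin) break
    z <- z / mean(z)
    v <- v * z
    if (max(v) < .Machine$double.xmin) {
      stop_degenerate("All predictor weights collapsed to zero.")
    }
    v <- v / mean(v)
    selected <- v > keep_threshold * max(v)
    if (!is.null(selected_prev) && identical(selected, selected_prev)) break
    selected_prev <- selected
  }
  selected <- v > keep_threshold * max(v)
  if (sum(selected) == 1L) {
    warn("IPW weights collapsed onto a single band.")
  }
  new_selection("ipw", scores = v, selected = selected,
                threshold = keep_threshold * max(v),
                wavelengths = sm$wavelengths,
                provenance = list(max_iter = max_iter,
                                  keep_threshold = keep_threshold,
                                  iterations = it, ncomp = ncomp))
}

# Variable importance in projection from a fitted nir_plsr model;
# mean(VIP^2) = 1 by construction.
vip_scores <- function(fit) {
  W <- fit$weights
  if (ncol(W) == 0L) return(rep(0, fit$dims[["p"]]))
  ss <- fit$y_loadings^2 * colSums(fit$scores^2)
  Wn2 <- sweep(W^2, 2L, colSums(W^2), `/`)
  sqrt(fit$dims[["p"]] * drop(Wn2 %*% ss) / sum(ss))
}

#' Regularized backward elimination (REP) selection
#'
#' Starting from the full spectrum, repeatedly drops the `drop_fraction`
#' of current bands with the lowest variable-importance-in-projection (VIP)
#' scores, recording the 10-fold cross-validated RMSE of a PLSR on each
#' candidate set, until `min_bands` is reached. The returned set is the one
#' minimizing CV RMSE.
#'
#' @param x Spectra tibble or matrix.
#' @param y Response.
#' @param drop_fraction Fraction of surviving bands dropped per step.
#' @param min_bands Smallest candidate set considered.
#' @param max_ncomp Components for the internal PLSR fits.
#' @param n_folds CV folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return A `nir_selection` object; scores are the elimination step at
#'   which each band would be dropped (higher = survives longer).
#' @export
select_rep <- function(x, y, drop_fraction = 0.1, min_bands = 10,
                       max_ncomp = 10, n_folds = 10, seed = 1) {
  drop_fraction <- check_fraction(drop_fraction, "drop_fraction", open_hi = TRUE)
  min_bands <- check_count(min_bands, "min_bands")
  sm <- spectra_matrix(x)
  X <- sm$values
  y <- as.numeric(y)
  p <- ncol(X)
  fold_stats <- make_fold_stats(X, y, n_folds, seed)
  active <- seq_len(p)
  drop_order <- rep(NA_integer_, p)
  candidates <- list()
  rmse <- numeric(0)
  step <- 0L
  repeat {
    step <- step + 1L
    k <- min(max_ncomp, nrow(X) - 2L, length(active))
    rmse <- c(rmse, cv_rmse_subset(fold_stats, X, y, active, k))
    candidates[[step]] <- active
    if (length(active) <= min_bands) break
    fit <- fit_plsr(X[, active, drop = FALSE], y, k)
    vip <- vip_scores(fit)
    n_drop <- max(1L, floor(drop_fraction * length(active)))
    n_drop <- min(n_drop, length(active) - min_bands)
    if (n_drop < 1L) n_drop <- length(active) - min_bands
    worst <- order(vip)[seq_len(max(n_drop, 1L))]
    drop_order[active[worst]] <- step
    active <- active[-worst]
  }
  best_step <- which.min(rmse)
  selected <- rep(FALSE, p)
  selected[candidates[[best_step]]] <- TRUE
  drop_order[is.na(drop_order)] <- step + 1L
  new_selection("rep", scores = as.numeric(drop_order), selected = selected,
                threshold = best_step, wavelengths = sm$wavelengths,
                provenance = list(drop_fraction = drop_fraction,
                                  min_bands = min_bands, n_steps = step,
                                  cv_rmse = rmse, seed = seed))
}

#' Genetic-algorithm wavelength selection
#'
#' Binary chromosomes act on contiguous windows of `window` bands (cutting
#' the search dimensionality). Fitness is the negative 5-fold cross-validated
#' RMSE of a PLSR on the active bands. Standard generational GA: tournament
#' selection of size 2, uniform crossover, per-bit mutation, elitism of one.
#' All-zero chromosomes are repaired by activating one random window.
#'
#' @param x Spectra tibble or matrix.
#' @param y Response.
#' @param pop_size Even population size, at least 4.
#' @param n_generations Generations to evolve.
#' @param mutation_rate Per-bit mutation probability.
#' @param window Bands per chromosome bit.
#' @param max_ncomp Components for the internal PLSR fits.
#' @param n_folds CV folds for the fitness (default 5).
#' @param seed Integer seed; the whole search is reproducible from it.
#' @return A `nir_selection` object; scores are the per-band selection
#'   frequency in the final population.
#' @export
select_ga <- function(x, y, pop_size = 64, n_generations = 100,
                      mutation_rate = 0.01, window = 4, max_ncomp = 10,
                      n_folds = 5, seed = 1) {
  pop_size <- check_count(pop_size, "pop_size", min = 4)
  if (pop_size %% 2L != 0L) stop_invalid("`pop_size` must be even.")
  n_generations <- check_count(n_generations, "n_generations")
  mutation_rate <- check_fraction(mutation_rate, "mutation_rate", open_lo = FALSE)
  sm <- spectra_matrix(x)
  X <- sm$values
  y <- as.numeric(y)
  p <- ncol(X)
  n_win <- ceiling(p / window)
  win_of_band <- rep(seq_len(n_win), each = window)[seq_len(p)]
  fold_stats <- make_fold_stats(X, y, n_folds, derive_seed(seed, 0L, 1L))

  set.seed(as.integer(seed %% 2147483647))
  pop <- matrix(stats::runif(pop_size * n_win) < 0.3, pop_size, n_win)
  repair <- function(chrom) {
    if (!any(chrom)) chrom[sample.int(n_win, 1L)] <- TRUE
    chrom
  }
  pop <- t(apply(pop, 1L, repair))
  cache <- new.env(parent = emptyenv())
  fitness_of <- function(chrom) {
    key <- paste(which(chrom), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    idx <- which(win_of_band %in% which(chrom))
    k <- min(max_ncomp, nrow(X) - 2L, length(idx))
    val <- -cv_rmse_subset(fold_stats, X, y, idx, k)
    cache[[key]] <- val
    val
  }
  fitness <- apply(pop, 1L, fitness_of)
  best_hist <- numeric(n_generations)
  for (g in seq_len(n_generations)) {
    elite <- which.max(fitness)
    new_pop <- matrix(FALSE, pop_size, n_win)
    new_pop[1L, ] <- pop[elite, ]
    for (i in seq.int(2L, pop_size)) {
      c1 <- sample.int(pop_size, 2L)
      p1 <- pop[c1[which.max(fitness[c1])], ]
      c2 <- sample.int(pop_size, 2L)
      p2 <- pop[c2[which.max(fitness[c2])], ]
      mix <- stats::runif(n_win) < 0.5
      child <- ifelse(mix, p1, p2)
      flip <- stats::runif(n_win) < mutation_rate
      child[flip] <- !child[flip]
      new_pop[i, ] <- repair(child)
    }
    pop <- new_pop
    fitness <- apply(pop, 1L, fitness_of)
    best_hist[g] <- max(fitness)
  }
  best <- pop[which.max(fitness), ]
  selected <- win_of_band %in% which(best)
  freq <- colMeans(pop)[win_of_band]
  new_selection("ga", scores = freq, selected = selected, threshold = 0.5,
                wavelengths = sm$wavelengths,
                provenance = list(pop_size = pop_size,
                                  n_generations = n_generations,
                                  mutation_rate = mutation_rate,
                                  window = window, seed = seed,
                                  best_fitness = best_hist))
}
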