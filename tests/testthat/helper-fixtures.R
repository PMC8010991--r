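# Fixtures are generated in code; nothing is read from disk.

# Random spectra-like matrix with a linear signal planted on a few bands.
planted_fixture <- function(n = 60, p = 40, bands = c(10, 20, 30),
                            coefs = c(2, -1.5, 1), noise_sd = 0.01,
                            seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, bands, drop = FALSE] %*% coefs) + rnorm(n, 0, noise_sd)
  list(X = X, y = y, bands = bands)
}

# Wide spectra tibble on a regular grid, filled with a supplied matrix.
as_spectra <- function(X, start = 1100, step = 6) {
  wl <- start + step * (seq_len(ncol(X)) - 1)
  nirherit:::spectra_tibble(X, wl, sprintf("T%04d", seq_len(nrow(X))))
}

# Small simulated trial shared by evaluation tests (moderate SNR).
small_trial <- function(n_families = 12, seed = 99) {
  design <- make_design(n_families, 3, 3)
  traits <- simulate_traits(design, seed = seed)
  spectra <- simulate_spectra(traits, seed = seed + 1)
  list(design = design, traits = traits, spectra = spectra)
}

# Spectra-like fixture with *correlated* informative band groups: latent
# concentrations expressed across adjacent bands, the way real absorption
# peaks span several grid points.
grouped_fixture <- function(n = 100, p = 40, groups = list(8:11, 23:26),
                            coefs = c(2, -1.5), band_noise = 0.3,
                            y_noise = 0.05, seed = 60) {
  set.seed(seed)
  Z <- matrix(rnorm(n * length(groups)), n, length(groups))
  X <- matrix(rnorm(n * p, 0, band_noise), n, p)
  for (g in seq_along(groups)) X[, groups[[g]]] <- X[, groups[[g]]] + Z[, g]
  y <- drop(Z %*% coefs) + rnorm(n, 0, y_noise)
  list(X = X, y = y, bands = unlist(groups))
}
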