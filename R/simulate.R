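# Synthetic half-sib trial generator: design, genetically structured traits,
# and trait-linked NIR absorbance spectra.

#' Build a balanced half-sib progeny-trial design
#'
#' Lays out `n_families` open-pollinated families in a randomized
#' complete-block style trial: `n_reps` replications, each holding
#' `trees_per_rep` trees of every family. The default sizes reproduce a
#' 50-family, 5-replication, 6-trees-per-plot trial of 1500 trees.
#'
#' @param n_families Number of half-sib families.
#' @param n_reps Number of replications (blocks).
#' @param trees_per_rep Trees of each family within one replication.
#' @return A tibble with columns `tree_id`, `family_id`, `replication_id`,
#'   `position_in_rep`; exactly `n_families * n_reps * trees_per_rep` rows.
#' @examples
#' make_design(3, 2, 4)
#' @export
make_design <- function(n_families = 50, n_reps = 5, trees_per_rep = 6) {
  n_families <- check_count(n_families, "n_families")
  n_reps <- check_count(n_reps, "n_reps")
  trees_per_rep <- check_count(trees_per_rep, "trees_per_rep")
  grid <- tidyr::expand_grid(
    family_id = seq_len(n_families),
    replication_id = seq_len(n_reps),
    position_in_rep = seq_len(trees_per_rep)
  )
  dplyr::mutate(grid,
                tree_id = sprintf("F%03d_R%d_T%d", .data$family_id,
                                  .data$replication_id, .data$position_in_rep),
                .before = 1L)
}

#' Trait-simulation parameters for ANTH, FLAV and NBI
#'
#' Defines the multivariate family + residual variance structure the trait
#' generator draws from. Defaults describe three leaf nutrition traits --
#' anthocyanin (`anth`, percent mass fraction), flavonoid (`flav`, percent
#' mass fraction) and the nitrogen balance index (`nbi`, unitless
#' chlorophyll/flavonoid ratio). Family-variance ratios are back-solved from
#' half-sib heritabilities 0.78/0.58/0.61 with multiplier k = 2.5
#' (q = h2/k: 0.312/0.232/0.244); the family-level correlation structure
#' (ANTH-FLAV 0.36, ANTH-NBI 0.11, FLAV-NBI 0.09) and phenotypic
#' correlations (0.16/0.09/0.12) follow the trial this generator emulates.
#'
#' @param mu Named per-trait means.
#' @param total_variance Named per-trait total (family + residual) variances.
#' @param family_ratio Named per-trait share of total variance attributed to
#'   families (sigma2_f / (sigma2_f + sigma2_e)).
#' @param family_correlation,phenotypic_correlation 3x3 correlation matrices
#'   (trait order `anth, flav, nbi`) at the family-effect and total-phenotype
#'   level; residual covariances are derived from the two.
#' @return A list of class `trait_params` with elements `trait_names`, `mu`,
#'   `sigma2_f`, `sigma2_e`, `cov_f`, `cov_e`.
#' @export
trait_params <- function(mu = c(anth = 0.5, flav = 0.8, nbi = 0.4),
                         total_variance = c(anth = 0.04, flav = 0.0324, nbi = 0.0036),
                         family_ratio = c(anth = 0.312, flav = 0.232, nbi = 0.244),
                         family_correlation = default_family_correlation(),
                         phenotypic_correlation = default_phenotypic_correlation()) {
  traits <- names(mu)
  if (is.null(traits) || !setequal(names(total_variance), traits) ||
      !setequal(names(family_ratio), traits)) {
    stop_invalid("`mu`, `total_variance` and `family_ratio` must share trait names.")
  }
  total_variance <- total_variance[traits]
  family_ratio <- family_ratio[traits]
  if (any(total_variance <= 0)) stop_invalid("Total variances must be positive.")
  if (any(family_ratio < 0 | family_ratio > 1)) {
    stop_invalid("`family_ratio` entries must lie in [0, 1].")
  }
  sigma2_f <- family_ratio * total_variance
  sigma2_e <- (1 - family_ratio) * total_variance
  sd_f <- sqrt(sigma2_f)
  sd_tot <- sqrt(total_variance)
  cov_f <- family_correlation * tcrossprod(sd_f)
  cov_p <- phenotypic_correlation * tcrossprod(sd_tot)
  cov_e <- cov_p - cov_f
  diag(cov_e) <- sigma2_e
  dimnames(cov_f) <- dimnames(cov_e) <- list(traits, traits)
  out <- list(trait_names = traits, mu = mu, sigma2_f = sigma2_f,
              sigma2_e = sigma2_e, cov_f = cov_f, cov_e = cov_e)
  class(out) <- "trait_params"
  validate_trait_params(out)
  out
}

default_family_correlation <- function() {
  m <- matrix(c(1, 0.36, 0.11,
                0.36, 1, 0.09,
                0.11, 0.09, 1), 3, 3)
  dimnames(m) <- list(c("anth", "flav", "nbi"), c("anth", "flav", "nbi"))
  m
}

default_phenotypic_correlation <- function() {
  m <- matrix(c(1, 0.16, 0.09,
                0.16, 1, 0.12,
                0.09, 0.12, 1), 3, 3)
  dimnames(m) <- list(c("anth", "flav", "nbi"), c("anth", "flav", "nbi"))
  m
}

validate_trait_params <- function(p) {
  for (nm in c("cov_f", "cov_e")) {
    m <- p[[nm]]
    if (!isSymmetric(unname(m), tol = 1e-8)) {
      stop_invalid(sprintf("`%s` must be symmetric.", nm))
    }
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop_invalid(sprintf("`%s` must be positive semi-definite.", nm))
    }
  }
  invisible(p)
}

# Square root of a PSD matrix (tolerates exactly singular matrices, e.g. a
# zero family covariance).
psd_sqrt <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1)) {
    stop_invalid("Covariance matrix must be positive semi-definite.")
  }
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate genetically structured trait values on a trial design
#'
#' Draws one multivariate family effect per family (covariance `cov_f`) and
#' one residual vector per tree (covariance `cov_e`), so that
#' `trait = mu + family effect + residual`. Concentration traits are kept
#' non-negative by redrawing the residual of offending trees (up to 100
#' attempts) rather than clipping, which would create a point mass at zero.
#' An implied chlorophyll column `chl = nbi * flav` is emitted for spectral
#' mixing (NBI being the chlorophyll-to-flavonoid ratio).
#'
#' @param design A design tibble from [make_design()].
#' @param params A [trait_params()] object.
#' @param seed Integer seed; the same seed reproduces the same table.
#' @return The design tibble with added columns `anth`, `flav`, `nbi`, `chl`.
#' @export
simulate_traits <- function(design, params = trait_params(), seed = 1) {
  if (!is.data.frame(design) || nrow(design) == 0L) {
    stop_invalid("`design` must be a non-empty design table.")
  }
  if (!all(c("family_id", "replication_id") %in% names(design))) {
    stop_schema("`design` must have `family_id` and `replication_id` columns.")
  }
  validate_trait_params(params)
  traits <- params$trait_names
  k <- length(traits)
  Lf <- psd_sqrt(params$cov_f)
  Le <- psd_sqrt(params$cov_e)
  fams <- sort(unique(design$family_id))
  n <- nrow(design)

  set.seed(as.integer(seed %% 2147483647))
  fam_eff <- matrix(rnorm(length(fams) * k), ncol = k) %*% Lf
  rownames(fam_eff) <- as.character(fams)
  res <- matrix(rnorm(n * k), ncol = k) %*% Le
  values <- matrix(params$mu[traits], n, k, byrow = TRUE) +
    fam_eff[as.character(design$family_id), , drop = FALSE] + res

  bad <- which(apply(values < 0, 1L, any))
  attempts <- 0L
  while (length(bad) > 0L && attempts < 100L) {
    res_new <- matrix(rnorm(length(bad) * k), ncol = k) %*% Le
    values[bad, ] <- matrix(params$mu[traits], length(bad), k, byrow = TRUE) +
      fam_eff[as.character(design$family_id[bad]), , drop = FALSE] + res_new
    bad <- bad[apply(values[bad, , drop = FALSE] < 0, 1L, any)]
    attempts <- attempts + 1L
  }
  if (length(bad) > 0L) {
    warn(sprintf("%d trees still negative after 100 redraws; clamped at 0.",
                 length(bad)))
    values[values < 0] <- 0
  }
  colnames(values) <- traits
  out <- dplyr::bind_cols(as_tibble(design), as_tibble(values))
  if (all(c("nbi", "flav") %in% traits)) {
    out$chl <- out$nbi * out$flav
  }
  out
}

#' Spectra-simulation parameters
#'
#' Describes the synthetic NIR measurement: a 234-band grid from 1100 to
#' 2498 nm in 6 nm steps (the instrument range 1100--2500 nm truncated to a
#' whole number of steps), additive Gaussian absorption features per analyte,
#' a linear baseline, per-scan multiplicative scatter and band noise, and
#' averaging of `n_scans` probe readings. Peak centers follow the wavelength
#' regions most informative for each trait in leaf NIR work: ANTH 2060, 2180,
#' 2270, 2330, 2440 nm; FLAV 1130 (moved in-grid from a sub-1100 nm feature),
#' 1235, 1950, 2220 nm; chlorophyll 1100, 1220, 1465, 1950, 2220 nm.
#' Chlorophyll carries the largest amplitude (it dominates leaf NIR
#' absorbance); amplitudes and noise were calibrated once so a default run
#' ranks validation accuracy ANTH > FLAV > NBI, with NBI hardest because it
#' enters the spectra only through the chlorophyll = NBI x FLAV product.
#'
#' @param wavelength_start First band (nm).
#' @param wavelength_step Grid step (nm).
#' @param n_bands Number of bands.
#' @param peaks Named list (one entry per analyte) of lists with `centers`
#'   (nm), `width` (Gaussian SD, nm) and `amplitudes` (per peak, unitless
#'   absorbance per unit concentration).
#' @param baseline_coeffs `c(intercept, slope)`; baseline absorbance is
#'   `intercept + slope * (wavelength - wavelength_start)`.
#' @param scatter_sd SD of the per-scan multiplicative (1 + a) and additive b
#'   scatter terms.
#' @param noise_sd SD of independent per-band scan noise.
#' @param n_scans Scans averaged into one stored spectrum.
#' @return A list of class `spectra_params`.
#' @export
spectra_params <- function(wavelength_start = 1100,
                           wavelength_step = 6,
                           n_bands = 234,
                           peaks = default_peaks(),
                           baseline_coeffs = c(0.3, 1e-4),
                           scatter_sd = 0.05,
                           noise_sd = 0.15,
                           n_scans = 3) {
  n_bands <- check_count(n_bands, "n_bands", min = 2)
  n_scans <- check_count(n_scans, "n_scans", min = 1)
  if (scatter_sd < 0 || noise_sd < 0) stop_invalid("Noise SDs must be >= 0.")
  wl_max <- wavelength_start + wavelength_step * (n_bands - 1)
  for (analyte in names(peaks)) {
    pk <- peaks[[analyte]]
    if (any(pk$centers < wavelength_start | pk$centers > wl_max)) {
      stop_invalid(sprintf("Peak centers for `%s` fall outside the wavelength range.",
                           analyte))
    }
    if (length(pk$amplitudes) == 1L) {
      peaks[[analyte]]$amplitudes <- rep(pk$amplitudes, length(pk$centers))
    } else if (length(pk$amplitudes) != length(pk$centers)) {
      stop_invalid(sprintf("`%s`: amplitudes must match centers.", analyte))
    }
  }
  structure(list(wavelength_start = wavelength_start,
                 wavelength_step = wavelength_step,
                 n_bands = n_bands, peaks = peaks,
                 baseline_coeffs = baseline_coeffs,
                 scatter_sd = scatter_sd, noise_sd = noise_sd,
                 n_scans = n_scans),
            class = "spectra_params")
}

default_peaks <- function() {
  list(
    anth = list(centers = c(2060, 2180, 2270, 2330, 2440), width = 25,
                amplitudes = 0.40),
    flav = list(centers = c(1130, 1235, 1950, 2220), width = 35,
                amplitudes = 0.12),
    chl = list(centers = c(1100, 1220, 1465, 1950, 2220), width = 25,
               amplitudes = 2.4)
  )
}

#' Simulate NIR spectra from trait concentrations
#'
#' Per tree, the noiseless absorbance is the concentration-weighted sum of
#' each analyte's Gaussian peak profile plus a linear baseline. Each of
#' `n_scans` scans perturbs it with multiplicative scatter `(1 + a) * A + b`
#' (`a`, `b` ~ Normal(0, scatter_sd)) and independent per-band noise; the
#' stored spectrum is the scan mean.
#'
#' @param traits A trait tibble from [simulate_traits()] (needs the analyte
#'   columns named in `params$peaks`, by default `anth`, `flav`, `chl`).
#' @param params A [spectra_params()] object.
#' @param seed Integer seed.
#' @return A wide spectra tibble: `tree_id` plus one `w<nm>` column per band.
#' @export
simulate_spectra <- function(traits, params = spectra_params(), seed = 1) {
  analytes <- names(params$peaks)
  missing_cols <- setdiff(analytes, names(traits))
  if (length(missing_cols) > 0L) {
    stop_schema(sprintf("Trait table lacks analyte column(s): %s.",
                        paste(missing_cols, collapse = ", ")))
  }
  wl <- params$wavelength_start +
    params$wavelength_step * (seq_len(params$n_bands) - 1)
  profiles <- vapply(analytes, function(a) {
    pk <- params$peaks[[a]]
    rowSums(vapply(seq_along(pk$centers), function(i) {
      pk$amplitudes[i] * exp(-(wl - pk$centers[i])^2 / (2 * pk$width^2))
    }, numeric(length(wl))))
  }, numeric(length(wl)))
  conc <- as.matrix(traits[analytes])
  baseline <- params$baseline_coeffs[1] +
    params$baseline_coeffs[2] * (wl - params$wavelength_start)
  clean <- conc %*% t(profiles) +
    matrix(baseline, nrow(conc), length(wl), byrow = TRUE)

  set.seed(as.integer(seed %% 2147483647))
  n <- nrow(clean)
  acc <- matrix(0, n, length(wl))
  for (s in seq_len(params$n_scans)) {
    a <- rnorm(n, 0, params$scatter_sd)
    b <- rnorm(n, 0, params$scatter_sd)
    noise <- matrix(rnorm(n * length(wl), 0, params$noise_sd), n, length(wl))
    acc <- acc + clean * (1 + a) + b + noise
  }
  ids <- if ("tree_id" %in% names(traits)) as.character(traits$tree_id) else
    as.character(seq_len(n))
  spectra_tibble(acc / params$n_scans, wl, ids)
}

#' Mark the subset of trees with laboratory trait measurements
#'
#' Samples `n_measured` trees without replacement, stratified by family:
#' whenever `n_measured` is at least the number of families, one tree per
#' family is guaranteed before the remainder is drawn uniformly.
#'
#' @param design A design tibble.
#' @param n_measured Number of trees to mark as measured.
#' @param seed Integer seed.
#' @return A logical vector along the rows of `design` with exactly
#'   `n_measured` `TRUE` entries.
#' @export
subsample_measured <- function(design, n_measured = 500, seed = 1) {
  n <- nrow(design)
  n_measured <- check_count(n_measured, "n_measured")
  if (n_measured > n) {
    stop_invalid(sprintf("`n_measured` (%d) exceeds the %d trees in the design.",
                         n_measured, n))
  }
  set.seed(as.integer(seed %% 2147483647))
  fams <- unique(design$family_id)
  chosen <- integer(0)
  if (n_measured >= length(fams)) {
    chosen <- vapply(fams, function(f) {
      rows <- which(design$family_id == f)
      rows[sample.int(length(rows), 1L)]
    }, integer(1))
  }
  remaining <- setdiff(seq_len(n), chosen)
  extra <- n_measured - length(chosen)
  if (extra > 0L) chosen <- c(chosen, remaining[sample.int(length(remaining), extra)])
  mask <- rep(FALSE, n)
  mask[chosen] <- TRUE
  mask
}
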