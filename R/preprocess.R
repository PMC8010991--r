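# Spectral pre-treatments: standard normal variate and Savitzky-Golay
# derivatives, plus the six-name dispatcher used by the evaluation grid.

#' Standard normal variate (SNV) transform
#'
#' Standardizes each spectrum (row) to mean 0 and sample SD 1 (denominator
#' n - 1), the classic correction for additive offset and multiplicative
#' scatter between samples.
#'
#' @param spectra Wide spectra tibble (or matrix); see [spectra_matrix()].
#' @return Spectra in the same wide-tibble form, wavelengths unchanged.
#' @export
snv <- function(spectra) {
  sm <- spectra_matrix(spectra)
  X <- sm$values
  mu <- rowMeans(X)
  s <- apply(X, 1L, sd)
  zero <- which(s < .Machine$double.eps^0.5 * pmax(abs(mu), 1))
  if (length(zero) > 0L) {
    stop_degenerate(sprintf(
      "SNV undefined for constant spectra; zero-variance sample(s): %s.",
      paste(sm$sample_ids[head(zero, 5L)], collapse = ", ")))
  }
  spectra_tibble((X - mu) / s, sm$wavelengths, sm$sample_ids)
}

# Savitzky-Golay convolution coefficients for the d-th derivative at the
# window center: least-squares polynomial fit of degree `polyorder` on
# offsets -h..h, differentiated at 0.
sg_coefficients <- function(window, polyorder, order) {
  h <- (window - 1L) %/% 2L
  offsets <- seq(-h, h)
  V <- outer(offsets, 0:polyorder, `^`)
  C <- solve(crossprod(V), t(V))
  C[order + 1L, ] * factorial(order)
}

#' Savitzky-Golay derivative
#'
#' Fits a least-squares polynomial of degree `polyorder` in a sliding window
#' of `window` points along each spectrum and evaluates its `order`-th
#' derivative at the window center. Output is expressed per nm (divided by
#' `step^order`, so values are grid-step independent) and trimmed to the
#' `n_bands - window + 1` interior bands where the full window fits; no data
#' is fabricated at the spectrum edges.
#'
#' @param spectra Wide spectra tibble or matrix.
#' @param order Derivative order, 1 or 2.
#' @param window Odd window size in grid points (default 15).
#' @param polyorder Polynomial degree; must satisfy
#'   `order <= polyorder < window`.
#' @return Wide spectra tibble over the trimmed wavelength grid.
#' @export
sg_derivative <- function(spectra, order, window = 15, polyorder = 2) {
  if (!order %in% c(1L, 2L)) stop_invalid("`order` must be 1 or 2.")
  window <- check_count(window, "window", min = 3)
  polyorder <- check_count(polyorder, "polyorder", min = 0)
  if (window %% 2L == 0L) stop_invalid("`window` must be odd.")
  if (polyorder < order) stop_invalid("`polyorder` must be >= `order`.")
  if (polyorder >= window) stop_invalid("`polyorder` must be < `window`.")
  sm <- spectra_matrix(spectra)
  p <- ncol(sm$values)
  if (window > p) stop_invalid("`window` exceeds the number of bands.")
  step <- grid_step(sm$wavelengths)
  cf <- sg_coefficients(window, polyorder, order) / step^order
  h <- (window - 1L) %/% 2L
  keep <- seq.int(h + 1L, p - h)
  out <- matrix(0, nrow(sm$values), length(keep))
  for (j in seq_len(window)) {
    out <- out + cf[j] * sm$values[, keep + (j - h - 1L), drop = FALSE]
  }
  spectra_tibble(out, sm$wavelengths[keep], sm$sample_ids)
}

#' The six pre-treatment methods compared by the pipeline
#' @return Character vector of method names.
#' @export
preprocess_methods <- function() c("raw", "snv", "d1", "d2", "snv_d1", "snv_d2")

#' Apply a named spectral pre-treatment
#'
#' Dispatches over the six-method vocabulary: `raw` (identity), `snv`,
#' first/second Savitzky-Golay derivatives (`d1`, `d2`), and SNV followed by
#' a derivative (`snv_d1`, `snv_d2`). All transforms are row-wise, so no
#' statistics leak between samples, and sample order is preserved.
#'
#' @param spectra Wide spectra tibble or matrix.
#' @param method One of [preprocess_methods()].
#' @param window,polyorder Savitzky-Golay settings for derivative methods.
#' @return Wide spectra tibble.
#' @export
preprocess <- function(spectra, method = "raw", window = 15, polyorder = 2) {
  if (length(method) != 1L || !method %in% preprocess_methods()) {
    stop_invalid(sprintf("Unknown preprocessing method `%s`; use one of %s.",
                         paste(method, collapse = ","),
                         paste(preprocess_methods(), collapse = ", ")))
  }
  switch(method,
    raw = if (is.matrix(spectra)) {
      sm <- spectra_matrix(spectra)
      spectra_tibble(sm$values, sm$wavelengths, sm$sample_ids)
    } else spectra,
    snv = snv(spectra),
    d1 = sg_derivative(spectra, 1L, window, polyorder),
    d2 = sg_derivative(spectra, 2L, window, polyorder),
    snv_d1 = sg_derivative(snv(spectra), 1L, window, polyorder),
    snv_d2 = sg_derivative(snv(spectra), 2L, window, polyorder)
  )
}
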