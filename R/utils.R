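# Internal helpers shared across modules.

stop_invalid <- function(msg, ...) {
  abort(msg, class = "nirherit_error_invalid_parameter", ...)
}

stop_schema <- function(msg, ...) {
  abort(msg, class = "nirherit_error_schema", ...)
}

stop_degenerate <- function(msg, ...) {
  abort(msg, class = "nirherit_error_degenerate", ...)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_invalid(sprintf("`%s` must be a whole number >= %d (got %s).",
                         name, min, paste(format(x), collapse = ", ")))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_lo = TRUE, open_hi = FALSE) {
  bad <- !is.numeric(x) || length(x) != 1L || is.na(x) ||
    (if (open_lo) x <= lo else x < lo) ||
    (if (open_hi) x >= hi else x > hi)
  if (bad) stop_invalid(sprintf("`%s` must lie in %s%g, %g%s (got %g).",
                                name, if (open_lo) "(" else "[", lo, hi,
                                if (open_hi) ")" else "]", x))
  as.numeric(x)
}

# All randomness flows from a single master seed. Stage/repetition sub-seeds
# are derived with a fixed affine-mod scheme so any repetition can be re-run
# in isolation; results stay below 2^31 - 1 (R's integer range).
derive_seed <- function(seed, index, stage = 0L) {
  seed <- as.double(seed %% 1000003L)
  as.integer((seed * 2039 + as.double(index) * 7919 + as.double(stage) * 104729 + 1) %%
               2147483647)
}

is_wavelength_name <- function(x) grepl("^w[0-9]+(\\.[0-9]+)?$", x)

#' Convert a wide spectra tibble to a numeric matrix
#'
#' Spectra travel through the package as wide tibbles: a `tree_id` column
#' followed by one `w<nm>` column per wavelength (the package's CSV dialect).
#' This helper extracts the numeric block and the wavelength grid.
#'
#' @param spectra A data frame with a `tree_id` column and `w<nm>` columns,
#'   or a plain numeric matrix (returned as is, with wavelengths taken from
#'   column names when they follow the `w<nm>` convention).
#' @return A list with `values` (samples x bands matrix), `wavelengths`
#'   (numeric, nm) and `sample_ids`.
#' @export
spectra_matrix <- function(spectra) {
  if (is.matrix(spectra)) {
    wl <- colnames(spectra)
    wavelengths <- if (!is.null(wl) && all(is_wavelength_name(wl))) {
      as.numeric(sub("^w", "", wl))
    } else {
      seq_len(ncol(spectra))
    }
    ids <- rownames(spectra) %||% as.character(seq_len(nrow(spectra)))
    return(list(values = unname(spectra), wavelengths = wavelengths, sample_ids = ids))
  }
  if (!is.data.frame(spectra)) {
    stop_schema("`spectra` must be a data frame or a numeric matrix.")
  }
  if (!"tree_id" %in% names(spectra)) {
    stop_schema("Spectra table must have a `tree_id` column.")
  }
  band_cols <- names(spectra)[is_wavelength_name(names(spectra))]
  if (length(band_cols) < 1L) {
    stop_schema("Spectra table has no `w<nm>` wavelength columns.")
  }
  wavelengths <- as.numeric(sub("^w", "", band_cols))
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop_schema("Wavelength columns must be strictly increasing.")
  }
  values <- as.matrix(spectra[band_cols])
  if (!is.numeric(values)) stop_schema("Wavelength columns must be numeric.")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop_schema(sprintf("Missing value in spectra at row %d, column %s.",
                        idx[1L], band_cols[idx[2L]]))
  }
  list(values = unname(values), wavelengths = wavelengths,
       sample_ids = as.character(spectra$tree_id))
}

# Inverse of spectra_matrix(): rebuild the wide tibble.
spectra_tibble <- function(values, wavelengths, sample_ids) {
  colnames(values) <- paste0("w", format(wavelengths, trim = TRUE, scientific = FALSE))
  dplyr::bind_cols(tibble(tree_id = sample_ids), as_tibble(values))
}

grid_step <- function(wavelengths) {
  steps <- diff(wavelengths)
  if (length(steps) == 0L) return(1)
  if (max(steps) - min(steps) > 1e-8 * max(abs(steps))) {
    stop_schema("Wavelength grid must be evenly spaced for derivative filters.")
  }
  steps[1L]
}
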