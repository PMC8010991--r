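# CSV readers/writers in the package's wide-spectra dialect, plus the YAML
# pipeline configuration.

#' Read a wide spectra CSV
#'
#' Expects a header `tree_id,w<nm>,...` with strictly increasing
#' wavelengths and a fully numeric body; a blank or non-numeric cell is an
#' error naming its location.
#'
#' @param path File path.
#' @return Wide spectra tibble.
#' @export
read_spectra <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    tree_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  if (!"tree_id" %in% names(out)) stop_schema("Missing `tree_id` column.")
  bad_names <- setdiff(names(out), c("tree_id"))
  not_wl <- bad_names[!is_wavelength_name(bad_names)]
  if (length(not_wl) > 0L) {
    stop_schema(sprintf("Non-wavelength column(s) in spectra file: %s.",
                        paste(head(not_wl, 5L), collapse = ", ")))
  }
  spectra_matrix(out)  # validates monotone grid and missing cells
  out
}

#' Write a wide spectra CSV
#' @param spectra Wide spectra tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  spectra_matrix(spectra)
  readr::write_csv(spectra, path, progress = FALSE)
  invisible(path)
}

#' Read a trait/design CSV
#' @param path File path.
#' @return Tibble.
#' @export
read_traits <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"tree_id" %in% names(out)) stop_schema("Missing `tree_id` column.")
  out
}

#' Default end-to-end pipeline configuration
#'
#' The simulate block reproduces the reference trial (50 families x 5
#' replications x 6 trees = 1500 trees; 500 with laboratory measurements);
#' the evaluate block runs the repeated-split protocol at a desk-scale 50
#' repetitions over all six pre-treatments, comparing the full spectrum with
#' sMC selection; the genetics block uses the half-sib multiplier k = 2.5.
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param n_rep Repetitions of the evaluation protocol.
#' @param selectors Selectors compared in the grid.
#' @param methods Preprocessing methods compared in the grid.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1, n_rep = 50,
                           selectors = c("none", "smc"),
                           methods = preprocess_methods()) {
  list(
    seed = seed,
    simulate = list(n_families = 50, n_reps = 5, trees_per_rep = 6,
                    n_measured = 500),
    evaluate = list(methods = methods, selectors = selectors,
                    n_rep = n_rep, frac_cal = 0.8, max_ncomp = 10,
                    window = 15, polyorder = 2),
    genetics = list(k = 2.5, se = TRUE, gain_fractions = c(0.1, 0.2, 0.3),
                    select_above_mean = c("anth", "flav", "nbi"))
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing blocks fall back to [default_config()] values; method and
#' selector names are validated against the registered vocabularies.
#'
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  if (is.null(cfg$seed)) stop_invalid("Config must set a master `seed`.")
  bad_m <- setdiff(cfg$evaluate$methods, preprocess_methods())
  if (length(bad_m) > 0L) {
    stop_invalid(sprintf("Unknown preprocessing method(s): %s.",
                         paste(bad_m, collapse = ", ")))
  }
  bad_s <- setdiff(cfg$evaluate$selectors, selector_methods())
  if (length(bad_s) > 0L) {
    stop_invalid(sprintf("Unknown selector(s): %s.",
                         paste(bad_s, collapse = ", ")))
  }
  cfg
}

#' Serialize a fitted PLSR model to JSON
#'
#' Stores the centering vectors, regression vector, per-component weights
#' and loadings and metadata; [read_plsr()] restores a model whose
#' predictions match the original exactly.
#'
#' @param model A `nir_plsr` model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plsr <- function(model, path) {
  if (!inherits(model, "nir_plsr")) stop_schema("`model` must be a `nir_plsr`.")
  payload <- list(
    x_mean = model$x_mean, y_mean = model$y_mean,
    weights = model$weights, loadings = model$loadings,
    y_loadings = model$y_loadings, coef_path = model$coef_path,
    coefficients = model$coefficients, ncomp = model$ncomp,
    wavelengths = model$wavelengths, dims = as.list(model$dims))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor")
  invisible(path)
}

#' Restore a PLSR model written by [write_plsr()]
#' @param path JSON file path.
#' @return A `nir_plsr` model (without training scores).
#' @export
read_plsr <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  # column-major matrices come back as one row per stored column
  as_mat <- function(m, ncol) {
    if (is.matrix(m)) t(m) else matrix(as.numeric(m), ncol = max(ncol, 1L))
  }
  structure(list(
    x_mean = as.numeric(p$x_mean), y_mean = as.numeric(p$y_mean),
    weights = as_mat(p$weights, p$ncomp), loadings = as_mat(p$loadings, p$ncomp),
    y_loadings = as.numeric(p$y_loadings),
    coef_path = as_mat(p$coef_path, p$ncomp),
    coefficients = as.numeric(p$coefficients),
    ncomp = as.integer(p$ncomp), wavelengths = as.numeric(p$wavelengths),
    scores = NULL,
    dims = c(n = as.integer(p$dims$n), p = as.integer(p$dims$p))
  ), class = "nir_plsr")
}
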