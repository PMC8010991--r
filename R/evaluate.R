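# The repeated calibration/validation protocol: random 80/20 splits, selector
# and component choice inside each split (leakage-safe), grid search over
# preprocessing x selector, ensemble prediction and residual diagnostics.

#' Run the repeated-split calibration/validation protocol
#'
#' For each of `n_rep` repetitions: draw a random calibration/validation
#' split (default 80/20), run the wavelength selector on the calibration
#' half only, choose the PLS component count by leave-one-out
#' cross-validation on the calibration half, fit, and score both halves.
#' Preprocessing is row-wise (it needs no fitting) and is applied once up
#' front. Every repetition is reproducible in isolation: its seed is derived
#' from the master seed and the repetition index by a fixed scheme.
#'
#' @param spectra Wide spectra tibble.
#' @param traits Tibble with `tree_id` and the response trait column.
#' @param trait Name of the response column in `traits`.
#' @param method Preprocessing method, one of [preprocess_methods()].
#' @param selector One of [selector_methods()] (`"none"` = full spectrum).
#' @param n_rep Number of repetitions (the reference protocol uses 200).
#' @param frac_cal Calibration fraction of each split.
#' @param seed Master seed.
#' @param max_ncomp Cap on PLS components.
#' @param window,polyorder Savitzky-Golay settings.
#' @param selector_args Extra arguments for the selector.
#' @return An object of class `nir_evaluation`: `records` (one row per
#'   repetition), `stability` (repetitions x bands logical matrix), `models`
#'   (per-repetition fitted pipelines), `config`, `wavelengths`.
#' @export
evaluate_pipeline <- function(spectra, traits, trait,
                              method = "raw", selector = "none",
                              n_rep = 200, frac_cal = 0.8, seed = 1,
                              max_ncomp = 10, window = 15, polyorder = 2,
                              selector_args = list()) {
  n_rep <- check_count(n_rep, "n_rep")
  frac_cal <- check_fraction(frac_cal, "frac_cal", open_hi = TRUE)
  if (!trait %in% names(traits)) {
    stop_schema(sprintf("Trait `%s` not found in the trait table.", trait))
  }
  data <- dplyr::inner_join(traits[c("tree_id", trait)], spectra, by = "tree_id")
  pp <- preprocess(data, method, window = window, polyorder = polyorder)
  sm <- spectra_matrix(pp)
  X <- sm$values
  y <- data[[trait]]
  n <- nrow(X)
  n_cal <- round(frac_cal * n)
  if (n_cal < 5L || n - n_cal < 5L) {
    stop_invalid("Both split halves need at least 5 samples.")
  }

  run_one <- function(r) {
    split_seed <- derive_seed(seed, r, 0L)
    sel_seed <- derive_seed(seed, r, 1L)
    set.seed(split_seed)
    idx_cal <- sort(sample.int(n, n_cal))
    idx_val <- setdiff(seq_len(n), idx_cal)
    sel <- rlang::exec(run_selector, X[idx_cal, , drop = FALSE], y[idx_cal],
                       method = selector, seed = sel_seed,
                       !!!selector_args)
    mask <- sel$selected
    Xc <- X[idx_cal, mask, drop = FALSE]
    pick <- loo_select_ncomp(Xc, y[idx_cal],
                             max_ncomp = min(max_ncomp, sum(mask), n_cal - 2L))
    k <- max(1L, pick$best)
    fit <- fit_plsr(Xc, y[idx_cal], k)
    pred_cal <- predict(fit, Xc)
    pred_val <- predict(fit, X[idx_val, mask, drop = FALSE])
    st_cal <- fit_stats(y[idx_cal], pred_cal)
    st_val <- fit_stats(y[idx_val], pred_val)
    list(
      record = tibble(
        rep = r, rep_seed = split_seed,
        split_hash = sum(idx_cal * seq_along(idx_cal)) %% 2147483647,
        n_components = fit$ncomp, n_selected = sum(mask),
        r2_cal = st_cal$r_squared, rmse_cal = st_cal$rmse,
        r2_val = st_val$r_squared, rmse_val = st_val$rmse,
        failed = FALSE, reason = NA_character_),
      mask = mask,
      model = list(mask = mask, x_mean = fit$x_mean, y_mean = fit$y_mean,
                   coefficients = fit$coefficients, ncomp = fit$ncomp)
    )
  }

  reps <- purrr::map(seq_len(n_rep), function(r) {
    tryCatch(run_one(r), error = function(e) {
      list(record = tibble(rep = r, rep_seed = derive_seed(seed, r, 0L),
                           split_hash = NA_real_, n_components = NA_integer_,
                           n_selected = NA_integer_, r2_cal = NA_real_,
                           rmse_cal = NA_real_, r2_val = NA_real_,
                           rmse_val = NA_real_, failed = TRUE,
                           reason = conditionMessage(e)),
           mask = rep(NA, ncol(X)), model = NULL)
    })
  })

  structure(list(
    records = dplyr::bind_rows(purrr::map(reps, "record")),
    stability = do.call(rbind, purrr::map(reps, "mask")),
    models = purrr::map(reps, "model"),
    wavelengths = sm$wavelengths,
    config = list(trait = trait, method = method, selector = selector,
                  n_rep = n_rep, frac_cal = frac_cal, seed = seed,
                  max_ncomp = max_ncomp, window = window,
                  polyorder = polyorder, selector_args = selector_args)
  ), class = "nir_evaluation")
}

#' @export
print.nir_evaluation <- function(x, ...) {
  ok <- !x$records$failed
  cat(sprintf("<nir_evaluation> %s | %s + %s | %d reps (%d ok)\n",
              x$config$trait, x$config$method, x$config$selector,
              nrow(x$records), sum(ok)))
  if (any(ok)) {
    cat(sprintf("  mean R2_val %.3f, mean RMSE_val %.4f\n",
                mean(x$records$r2_val[ok]), mean(x$records$rmse_val[ok])))
  }
  invisible(x)
}

#' Summarize a repeated-split evaluation
#'
#' Mean, min, max and empirical 2.5/97.5 percentile bands of the four fit
#' statistics across successful repetitions (the percentile band is how the
#' protocol's "95% confidence intervals" are read).
#'
#' @param ev A `nir_evaluation` object.
#' @return A tibble with one row per statistic.
#' @export
summarise_evaluation <- function(ev) {
  rec <- ev$records[!ev$records$failed, ]
  if (nrow(rec) == 0L) stop_degenerate("All repetitions failed; nothing to summarize.")
  long <- tidyr::pivot_longer(rec[c("r2_cal", "rmse_cal", "r2_val", "rmse_val")],
                              dplyr::everything(),
                              names_to = "statistic", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, .data$statistic),
    mean = mean(.data$value), min = min(.data$value), max = max(.data$value),
    p2.5 = unname(quantile(.data$value, 0.025, type = 7)),
    p97.5 = unname(quantile(.data$value, 0.975, type = 7)),
    .groups = "drop")
}

#' @export
#' @method tidy nir_evaluation
tidy.nir_evaluation <- function(x, ...) x$records

#' @export
#' @method glance nir_evaluation
glance.nir_evaluation <- function(x, ...) {
  rec <- x$records[!x$records$failed, ]
  tibble(trait = x$config$trait, method = x$config$method,
         selector = x$config$selector, n_rep = nrow(x$records),
         n_ok = nrow(rec),
         mean_r2_cal = mean(rec$r2_cal), mean_rmse_cal = mean(rec$rmse_cal),
         mean_r2_val = mean(rec$r2_val), mean_rmse_val = mean(rec$rmse_val),
         min_r2_val = if (nrow(rec)) min(rec$r2_val) else NA_real_,
         max_r2_val = if (nrow(rec)) max(rec$r2_val) else NA_real_,
         mean_n_components = mean(rec$n_components),
         mean_n_selected = mean(rec$n_selected))
}

#' Per-band selection frequency across repetitions
#'
#' @param ev A `nir_evaluation` object.
#' @return A tibble with `wavelength` and `frequency` (share of repetitions
#'   selecting the band).
#' @export
selection_stability <- function(ev) {
  ok <- !ev$records$failed
  tibble(wavelength = ev$wavelengths,
         frequency = colMeans(ev$stability[ok, , drop = FALSE]))
}

#' Grid search over preprocessing methods and selectors
#'
#' Evaluates every (method, selector) cell with the identical sequence of
#' calibration/validation splits (the split seed depends only on the master
#' seed and repetition index), so cells are compared paired. The best cell
#' maximizes mean validation R^2; ties break toward lower mean validation
#' RMSE, then toward the earlier entry in `methods`/`selectors` (simpler
#' preprocessing first).
#'
#' @param spectra,traits,trait,n_rep,frac_cal,seed,max_ncomp,window,polyorder,selector_args
#'   As in [evaluate_pipeline()].
#' @param methods Preprocessing methods to compare.
#' @param selectors Selectors to compare.
#' @return An object of class `nir_grid`: `summary` tibble (one row per
#'   cell), `best` (list with `method`, `selector`), `evaluations` (named
#'   list of `nir_evaluation` objects).
#' @export
grid_search <- function(spectra, traits, trait,
                        methods = preprocess_methods(),
                        selectors = "none",
                        n_rep = 50, frac_cal = 0.8, seed = 1,
                        max_ncomp = 10, window = 15, polyorder = 2,
                        selector_args = list()) {
  if (length(methods) == 0L || length(selectors) == 0L) {
    stop_invalid("`methods` and `selectors` must be non-empty.")
  }
  cells <- tidyr::expand_grid(method = methods, selector = selectors)
  evals <- purrr::pmap(cells, function(method, selector) {
    evaluate_pipeline(spectra, traits, trait, method = method,
                      selector = selector, n_rep = n_rep,
                      frac_cal = frac_cal, seed = seed, max_ncomp = max_ncomp,
                      window = window, polyorder = polyorder,
                      selector_args = selector_args)
  })
  names(evals) <- paste(cells$method, cells$selector, sep = "+")
  summary <- dplyr::bind_rows(purrr::map(evals, glance))
  ranked <- dplyr::arrange(
    dplyr::mutate(summary,
                  .m = match(.data$method, methods),
                  .s = match(.data$selector, selectors)),
    dplyr::desc(.data$mean_r2_val), .data$mean_rmse_val, .data$.m, .data$.s)
  best <- list(method = ranked$method[1L], selector = ranked$selector[1L])
  structure(list(summary = summary, best = best, evaluations = evals,
                 trait = trait),
            class = "nir_grid")
}

#' @export
print.nir_grid <- function(x, ...) {
  cat(sprintf("<nir_grid> trait %s: %d cells; best %s + %s\n", x$trait,
              nrow(x$summary), x$best$method, x$best$selector))
  print(x$summary[c("method", "selector", "mean_r2_val", "mean_rmse_val")])
  invisible(x)
}

#' @export
#' @method tidy nir_grid
tidy.nir_grid <- function(x, ...) x$summary

#' Ensemble prediction with per-sample uncertainty
#'
#' Applies every successful per-repetition model of an evaluation to new
#' spectra and returns, per sample, the ensemble mean and standard deviation
#' of the predictions -- the per-tree error bar of the repeated-split
#' protocol.
#'
#' @param ev A `nir_evaluation` object (its preprocessing is re-applied to
#'   `spectra`).
#' @param spectra Wide spectra tibble for the samples to predict.
#' @return A tibble with `tree_id`, `pred`, `pred_sd`.
#' @export
ensemble_predict <- function(ev, spectra) {
  models <- purrr::compact(ev$models)
  if (length(models) < 2L) stop_invalid("Ensemble prediction needs >= 2 models.")
  pp <- preprocess(spectra, ev$config$method, window = ev$config$window,
                   polyorder = ev$config$polyorder)
  sm <- spectra_matrix(pp)
  if (ncol(sm$values) != length(ev$wavelengths)) {
    stop_schema("New spectra band space does not match the evaluation's.")
  }
  preds <- vapply(models, function(m) {
    Xs <- sm$values[, m$mask, drop = FALSE]
    drop(sweep(Xs, 2L, m$x_mean) %*% m$coefficients) + m$y_mean
  }, numeric(nrow(sm$values)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  tibble(tree_id = sm$sample_ids,
         pred = rowMeans(preds),
         pred_sd = apply(preds, 1L, sd))
}

#' Residual diagnostics table
#'
#' @param y Measured values.
#' @param yhat_mean Ensemble mean predictions.
#' @param yhat_sd Ensemble prediction SDs (optional).
#' @return A tibble with `measured`, `predicted`, `predicted_sd`, `residual`
#'   (= measured - predicted).
#' @export
residual_table <- function(y, yhat_mean, yhat_sd = NULL) {
  if (length(y) != length(yhat_mean)) stop_schema("Lengths differ.")
  yhat_sd <- yhat_sd %||% rep(NA_real_, length(y))
  if (length(yhat_sd) != length(y)) stop_schema("`yhat_sd` length differs.")
  tibble(measured = as.numeric(y), predicted = as.numeric(yhat_mean),
         predicted_sd = as.numeric(yhat_sd),
         residual = as.numeric(y) - as.numeric(yhat_mean))
}
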