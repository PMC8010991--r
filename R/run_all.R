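# End-to-end pipeline: simulate -> evaluate -> predict -> genetics -> select.

#' Run the full spectroscopy-to-breeding pipeline
#'
#' Chains every stage under one output directory: simulate the half-sib
#' trial (design, traits, spectra, measured subset); grid-search
#' preprocessing x selector on the measured trees with the repeated-split
#' protocol; ensemble-predict the unmeasured trees with the best model per
#' trait; estimate variance components, heritability, correlations and
#' breeding values on the combined (measured + predicted) trait table; apply
#' the multi-trait family-selection rules and realized-gain fractions. A
#' manifest records the configuration, derived stage seeds and every file
#' written. All numeric artifacts are deterministic functions of the
#' configuration.
#'
#' @param config Configuration list (see [default_config()] /
#'   [read_config()]).
#' @param out_dir Output directory (created if needed).
#' @param traits Trait columns to model.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results (`grids`, `genetics`, `predictions`).
#' @export
run_all <- function(config = default_config(), out_dir, traits = c("anth", "flav", "nbi"),
                    quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  say <- function(fmt, ...) if (!quiet) inform(sprintf(fmt, ...))
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(obj, path, progress = FALSE)
    files <<- c(files, name)
    path
  }
  seed <- config$seed
  stage_seeds <- list(traits = derive_seed(seed, 1L, 10L),
                      spectra = derive_seed(seed, 2L, 10L),
                      measured = derive_seed(seed, 3L, 10L),
                      evaluate = derive_seed(seed, 4L, 10L))

  say("stage simulate: %d families x %d reps x %d trees",
      config$simulate$n_families, config$simulate$n_reps,
      config$simulate$trees_per_rep)
  design <- make_design(config$simulate$n_families, config$simulate$n_reps,
                        config$simulate$trees_per_rep)
  tp <- config$simulate$trait_params %||% trait_params()
  sp <- config$simulate$spectra_params %||% spectra_params()
  trait_tbl <- simulate_traits(design, tp, seed = stage_seeds$traits)
  spectra <- simulate_spectra(trait_tbl, sp, seed = stage_seeds$spectra)
  measured <- subsample_measured(design, config$simulate$n_measured,
                                 seed = stage_seeds$measured)
  emit(design, "design.csv")
  emit(trait_tbl[measured, c("tree_id", traits)], "traits_measured.csv")
  emit(trait_tbl, "traits_true_synthetic.csv")
  write_spectra(spectra, file.path(out_dir, "spectra.csv"))
  files <- c(files, "spectra.csv")

  ev_cfg <- config$evaluate
  grids <- list()
  predictions <- list()
  combined <- trait_tbl[c("tree_id", "family_id", "replication_id")]
  for (tr in traits) {
    # Two-stage comparison, as a field study would run it: preprocessing
    # methods are compared on the full spectrum first, then the wavelength
    # selectors are compared on the winning pre-treatment.
    say("stage evaluate (%s): %d preprocessing methods, %d reps", tr,
        length(ev_cfg$methods), ev_cfg$n_rep)
    grid_pp <- grid_search(spectra[measured, ],
                           trait_tbl[measured, c("tree_id", tr)],
                           tr, methods = ev_cfg$methods, selectors = "none",
                           n_rep = ev_cfg$n_rep, frac_cal = ev_cfg$frac_cal,
                           seed = stage_seeds$evaluate,
                           max_ncomp = ev_cfg$max_ncomp,
                           window = ev_cfg$window, polyorder = ev_cfg$polyorder)
    extra_sel <- setdiff(ev_cfg$selectors, "none")
    if (length(extra_sel) > 0L) {
      say("stage evaluate (%s): selectors %s on %s", tr,
          paste(extra_sel, collapse = ","), grid_pp$best$method)
      grid_sel <- grid_search(spectra[measured, ],
                              trait_tbl[measured, c("tree_id", tr)],
                              tr, methods = grid_pp$best$method,
                              selectors = extra_sel, n_rep = ev_cfg$n_rep,
                              frac_cal = ev_cfg$frac_cal,
                              seed = stage_seeds$evaluate,
                              max_ncomp = ev_cfg$max_ncomp,
                              window = ev_cfg$window,
                              polyorder = ev_cfg$polyorder)
      evals <- c(grid_pp$evaluations, grid_sel$evaluations)
      summary <- dplyr::bind_rows(grid_pp$summary, grid_sel$summary)
      ranked <- dplyr::arrange(summary, dplyr::desc(.data$mean_r2_val),
                               .data$mean_rmse_val)
      grid <- structure(list(summary = summary,
                             best = list(method = ranked$method[1L],
                                         selector = ranked$selector[1L]),
                             evaluations = evals, trait = tr),
                        class = "nir_grid")
    } else {
      grid <- grid_pp
    }
    grids[[tr]] <- grid
    best_ev <- grid$evaluations[[paste(grid$best$method, grid$best$selector,
                                       sep = "+")]]
    emit(dplyr::mutate(grid$summary, trait = tr, .before = 1L),
         sprintf("grid_summary_%s.csv", tr))
    emit(dplyr::mutate(best_ev$records, trait = tr, .before = 1L),
         sprintf("records_best_%s.csv", tr))
    emit(selection_stability(best_ev), sprintf("stability_best_%s.csv", tr))

    say("stage predict (%s): best = %s + %s", tr, grid$best$method,
        grid$best$selector)
    pred <- ensemble_predict(best_ev, spectra[!measured, ])
    predictions[[tr]] <- pred
    emit(pred, sprintf("predictions_%s.csv", tr))
    filled <- numeric(nrow(trait_tbl))
    filled[measured] <- trait_tbl[[tr]][measured]
    filled[!measured] <- pred$pred
    combined[[tr]] <- filled
  }
  combined$source <- ifelse(measured, "measured", "predicted")
  emit(combined, "traits_combined.csv")

  say("stage genetics: k = %g on %d trees", config$genetics$k, nrow(combined))
  gen <- genetic_summary(combined, traits = traits, k = config$genetics$k,
                         se = isTRUE(config$genetics$se))
  bv <- gen$breeding_values
  emit(bv, "breeding_values.csv")
  gains <- tidyr::expand_grid(trait = traits,
                              top_fraction = config$genetics$gain_fractions)
  gains$gain <- purrr::map2_dbl(gains$trait, gains$top_fraction,
                                ~realized_gain(bv, .y, trait = .x))
  emit(gains, "realized_gains.csv")
  rules <- config$genetics$select_above_mean
  sel_af <- select_families(bv, setdiff(rules, "nbi"))
  sel_all <- select_families(bv, rules)
  selection_report <- list(
    rules_anth_flav = setdiff(rules, "nbi"),
    n_selected_anth_flav = nrow(sel_af),
    families_anth_flav = sel_af$family_id,
    rules_all = rules,
    n_selected_all = nrow(sel_all),
    families_all = sel_all$family_id)
  jsonlite::write_json(
    list(components = gen$components, correlations = gen$correlations,
         k = gen$k),
    file.path(out_dir, "genetics_summary.json"), dataframe = "rows",
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(selection_report,
                       file.path(out_dir, "selection_report.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, "genetics_summary.json", "selection_report.json")

  manifest <- list(
    package = "nirherit",
    version = as.character(utils::packageVersion("nirherit")),
    config = config, stage_seeds = stage_seeds, files = sort(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %d artifacts in %s", length(files) + 1L, out_dir)
  invisible(list(manifest = manifest, grids = grids, genetics = gen,
                 predictions = predictions,
                 selection_report = selection_report))
}
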