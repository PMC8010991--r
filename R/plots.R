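# ggplot2 views of the pipeline's result objects.

#' @describeIn evaluate_pipeline Boxplot of the four fit statistics across
#'   repetitions (the repeated-split uncertainty view).
#' @param object,x A `nir_evaluation` object.
#' @param ... Unused.
#' @export
#' @method autoplot nir_evaluation
autoplot.nir_evaluation <- function(object, ...) {
  rec <- object$records[!object$records$failed, ]
  long <- tidyr::pivot_longer(rec[c("r2_cal", "rmse_cal", "r2_val", "rmse_val")],
                              dplyr::everything(),
                              names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$statistic)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(
      title = sprintf("%s | %s + %s (%d repetitions)", object$config$trait,
                      object$config$method, object$config$selector, nrow(rec)),
      x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn run_selector Importance scores along the wavelength axis with
#'   the selected bands highlighted.
#' @param object,x A `nir_selection` object.
#' @param ... Unused.
#' @export
#' @method autoplot nir_selection
autoplot.nir_selection <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength, y = .data$score)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = df[df$selected, ], colour = "red", size = 0.8) +
    ggplot2::labs(title = sprintf("%s selection: %d bands", object$method,
                                  sum(df$selected)),
                  x = "wavelength (nm)", y = "importance score") +
    ggplot2::theme_minimal()
}

#' @describeIn genetic_summary Family breeding values ranked per trait.
#' @param object,x A `nir_genetics` object.
#' @param ... Unused.
#' @export
#' @method autoplot nir_genetics
autoplot.nir_genetics <- function(object, ...) {
  bv <- object$breeding_values
  long <- tidyr::pivot_longer(bv, dplyr::starts_with("bv_"),
                              names_to = "trait", values_to = "bv",
                              names_prefix = "bv_")
  long <- dplyr::mutate(dplyr::group_by(long, .data$trait),
                        rank = rank(-.data$bv, ties.method = "first"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$bv)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_wrap(~.data$trait, scales = "free_y") +
    ggplot2::labs(x = "family rank", y = "breeding value (trait units)") +
    ggplot2::theme_minimal()
}

#' Measured-versus-predicted plot with ensemble error bars
#'
#' @param residuals A tibble from [residual_table()].
#' @param trait Label for the axes.
#' @return A ggplot object.
#' @export
plot_measured_predicted <- function(residuals, trait = "trait") {
  ggplot2::ggplot(residuals,
                  ggplot2::aes(x = .data$measured, y = .data$predicted)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$predicted - .data$predicted_sd,
                                        ymax = .data$predicted + .data$predicted_sd),
                           linewidth = 0.2, colour = "grey60", na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = sprintf("measured %s", trait),
                  y = sprintf("predicted %s", trait)) +
    ggplot2::theme_minimal()
}

#' Selection-frequency map across repetitions
#'
#' @param ev A `nir_evaluation` object.
#' @return A ggplot object showing the share of repetitions selecting each
#'   band.
#' @export
plot_selection_stability <- function(ev) {
  ggplot2::ggplot(selection_stability(ev),
                  ggplot2::aes(x = .data$wavelength, y = .data$frequency)) +
    ggplot2::geom_col(width = 4) +
    ggplot2::labs(x = "wavelength (nm)",
                  y = "selection frequency across repetitions") +
    ggplot2::theme_minimal()
}
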