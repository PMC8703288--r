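#' Plot an extracted ion chromatogram
#'
#' @param xic XIC tibble from [extract_xic()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_xic <- function(xic, title = NULL) {
  ggplot2::ggplot(xic, ggplot2::aes(x = .data$rt_min, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "retention time (min)", y = "intensity",
                  title = title) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot calibration_fit
#' @export
autoplot.calibration_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$conc_um, y = .data$area)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept) +
    ggplot2::geom_vline(xintercept = c(object$lod_um, object$loq_um),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "concentration (µM)", y = "peak area",
                  title = object$analyte,
                  subtitle = sprintf("y = %.3g x, r = %.4f, LOD %.3g / LOQ %.3g µM",
                                     object$slope, object$r,
                                     object$lod_um, object$loq_um)) +
    ggplot2::theme_minimal()
}

#' Bar plot of per-cell amounts by condition
#'
#' Condition means with standard-deviation error bars, the usual rendering
#' of osmolyte salinity experiments.
#'
#' @param quant Quantification tibble from [quantify_samples()].
#' @return A ggplot object.
#' @export
plot_condition_summary <- function(quant) {
  s <- dplyr::summarise(dplyr::group_by(quant, .data$condition),
                        mean = mean(.data$fmol_per_cell),
                        sd = stats::sd(.data$fmol_per_cell),
                        .groups = "drop")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "black", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "fmol / cell") +
    ggplot2::theme_minimal()
}
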