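#' Fit an external calibration curve
#'
#' Least-squares calibration of peak area against concentration, through the
#' origin by default (matching the usual zero-intercept reporting of
#' external osmolyte calibrations). The correlation `r` is the Pearson
#' correlation of concentration and area; the residual standard deviation
#' uses the fit's residual degrees of freedom (n - 1 through the origin,
#' n - 2 otherwise); detection and quantification limits follow the ICH
#' convention LOD = 3.3 sigma / slope and LOQ = 10 sigma / slope.
#'
#' @param data Data frame with columns `conc_um` (uM, > 0) and `area`.
#'   At least 3 points with non-identical concentrations are required.
#' @param through_origin Fit `area ~ 0 + conc_um` (default) or with
#'   intercept.
#' @param analyte_name Optional analyte label stored in the fit.
#'
#' @return An object of class `"calibration_fit"` with fields `slope`,
#'   `intercept`, `r`, `residual_sd`, `lod_um`, `loq_um`, `n`, `data`.
#'   Supports [generics::tidy()], [generics::glance()], `print()` and
#'   [ggplot2::autoplot()].
#' @examples
#' pts <- data.frame(conc_um = c(1, 2, 5, 10), area = 2 * c(1, 2, 5, 10))
#' fit_calibration(pts)
#' @export
fit_calibration <- function(data, through_origin = TRUE,
                            analyte_name = NULL) {
  if (!all(c("conc_um", "area") %in% names(data))) {
    stop("`data` needs columns conc_um and area", call. = FALSE)
  }
  if (nrow(data) < 3L) stop("at least 3 calibration points required",
                            call. = FALSE)
  if (any(data$conc_um <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (length(unique(data$conc_um)) < 2L) {
    stop("calibration concentrations are all identical", call. = FALSE)
  }
  fit <- if (through_origin) {
    stats::lm(area ~ 0 + conc_um, data = data)
  } else {
    stats::lm(area ~ conc_um, data = data)
  }
  co <- stats::coef(fit)
  slope <- unname(co[["conc_um"]])
  if (slope <= 0) stop("non-positive calibration slope", call. = FALSE)
  sigma <- sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit))
  structure(list(
    analyte = analyte_name,
    slope = slope,
    intercept = if (through_origin) 0 else unname(co[["(Intercept)"]]),
    through_origin = through_origin,
    r = stats::cor(data$conc_um, data$area),
    residual_sd = sigma,
    lod_um = 3.3 * sigma / slope,
    loq_um = 10 * sigma / slope,
    n = nrow(data),
    data = tibble::as_tibble(data[, c("conc_um", "area")])
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration>", if (!is.null(x$analyte)) x$analyte else "", "\n")
  cat(sprintf("  y = %.4g x%s   (n = %d, r = %.4f)\n", x$slope,
              if (x$through_origin) "" else sprintf(" %+.4g", x$intercept),
              x$n, x$r))
  cat(sprintf("  LOD = %.3g uM, LOQ = %.3g uM\n", x$lod_um, x$loq_um))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy calibration_fit
#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(term = c(if (!x$through_origin) "(Intercept)", "slope"),
                 estimate = c(if (!x$through_origin) x$intercept, x$slope))
}

#' @method glance calibration_fit
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, r = x$r, residual_sd = x$residual_sd,
                 lod_um = x$lod_um, loq_um = x$loq_um, n = x$n)
}

#' Convert a peak area to a concentration with censoring
#'
#' `concentration = area / slope`; values below the curve's LOD are flagged
#' `"below_lod"`, values between LOD and LOQ `"below_loq"` (the "+" of
#' survey tables), and the rest `"quantifiable"`.
#'
#' @param area Non-negative peak area(s).
#' @param fit A [fit_calibration()] object.
#' @return A tibble with columns `conc_um` and `censoring`.
#' @export
concentration_from_area <- function(area, fit) {
  if (any(area < 0)) stop("area must be >= 0", call. = FALSE)
  conc <- area / fit$slope
  censoring <- dplyr::case_when(
    conc < fit$lod_um ~ "below_lod",
    conc < fit$loq_um ~ "below_loq",
    TRUE ~ "quantifiable"
  )
  tibble::tibble(conc_um = conc, censoring = censoring)
}
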