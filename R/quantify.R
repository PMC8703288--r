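#' Per-cell amount from an extract concentration
#'
#' Converts a measured concentration of the injected solution back to the
#' amount per cell harvested:
#' `fmol/cell = conc_um * dilution * extract_ml * 1e6 / cells`
#' (1 uM in 1 mL is 1e6 fmol).
#'
#' @param conc_um Measured concentration of the injected solution (uM).
#' @param cells Number of cells harvested onto the filter (> 0).
#' @param extract_ml Extract volume in mL (default 1).
#' @param dilution Dilution factor applied between extract and injection
#'   (default 3).
#' @return Per-cell amount in fmol/cell.
#' @examples
#' per_cell_amount(1, cells = 1e7)  # 0.1 fmol/cell at default volumes/dilution
#' @export
per_cell_amount <- function(conc_um, cells, extract_ml = 1, dilution = 3) {
  if (any(cells <= 0)) stop("cells must be > 0", call. = FALSE)
  if (any(extract_ml <= 0) || any(dilution <= 0)) {
    stop("extract_ml and dilution must be > 0", call. = FALSE)
  }
  conc_um * dilution * extract_ml * 1e6 / cells
}

#' Intracellular concentration from a per-cell amount
#'
#' `fmol/cell / pL = mM` exactly (1e-15 mol over 1e-12 L).
#'
#' @param fmol_per_cell Per-cell amount (fmol/cell).
#' @param cell_volume_pl Cell volume in pL (> 0).
#' @return Intracellular concentration in mM.
#' @export
intracellular_concentration <- function(fmol_per_cell, cell_volume_pl) {
  if (any(cell_volume_pl <= 0)) stop("cell_volume_pl must be > 0", call. = FALSE)
  fmol_per_cell / cell_volume_pl
}

#' Cell volume from a geometric shape
#'
#' Standard solid volumes used for microalgal biovolume estimation from
#' microscopy dimensions. 1 um^3 = 1 fL = 1e-3 pL.
#'
#' @param shape One of `"sphere"` (needs `d`), `"cylinder"` (`d`, `h`) or
#'   `"prolate_spheroid"` (`d`, `h`).
#' @param d Diameter in um.
#' @param h Height / long axis in um (cylinder and spheroid).
#' @return Volume in pL.
#' @examples
#' cell_volume_from_shape("cylinder", d = 10, h = 10)  # 0.7854 pL
#' @export
cell_volume_from_shape <- function(shape = c("sphere", "cylinder",
                                             "prolate_spheroid"),
                                   d, h = NULL) {
  shape <- match.arg(shape)
  if (d <= 0 || (!is.null(h) && h <= 0)) {
    stop("dimensions must be > 0", call. = FALSE)
  }
  um3 <- switch(shape,
    sphere = pi / 6 * d^3,
    cylinder = {
      if (is.null(h)) stop("cylinder needs `h`", call. = FALSE)
      pi / 4 * d^2 * h
    },
    prolate_spheroid = {
      if (is.null(h)) stop("prolate_spheroid needs `h`", call. = FALSE)
      pi / 6 * d^2 * h
    }
  )
  um3 * 1e-3
}

#' Quantify an analyte across the samples of an experiment
#'
#' The targeted quantification chain: for every sample run, extract the ion
#' chromatogram at the analyte m/z, integrate the peak around the analyte
#' retention time, convert the area to a concentration through the
#' calibration curve (with LOD/LOQ censoring), then to fmol/cell using each
#' sample's harvest context, and finally to intracellular mM through the
#' cell volume.
#'
#' @param experiment Sample tibble from [simulate_experiment()] (or any
#'   tibble with columns `sample_id`, `condition`, `replicate`,
#'   `cells_filtered`, `extract_ml`, `dilution`, `cell_volume_pl`, `run`).
#' @param analyte_def One-row analyte tibble ([analyte()]).
#' @param fit Calibration fit for this analyte ([fit_calibration()]).
#' @param tol_ppm XIC tolerance (default 5 ppm).
#' @param rt_halfwidth Integration half-window around the analyte retention
#'   time, minutes (default 0.3).
#'
#' @return A tibble with one row per sample: `sample_id`, `condition`,
#'   `replicate`, `analyte`, `area`, `conc_um`, `censoring`,
#'   `fmol_per_cell`, `mm`.
#' @export
quantify_samples <- function(experiment, analyte_def, fit, tol_ppm = 5,
                             rt_halfwidth = 0.3) {
  needed <- c("sample_id", "condition", "replicate", "cells_filtered",
              "extract_ml", "dilution", "cell_volume_pl", "run")
  missing <- setdiff(needed, names(experiment))
  if (length(missing) > 0L) {
    stop("experiment table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  window <- analyte_def$rt_min + c(-1, 1) * rt_halfwidth
  areas <- purrr::map_dbl(experiment$run, function(run) {
    xic <- extract_xic(run, analyte_def$mz, tol_ppm = tol_ppm)
    max(integrate_peak(xic, window), 0)
  })
  conc <- concentration_from_area(areas, fit)
  tibble::tibble(
    sample_id = experiment$sample_id,
    condition = experiment$condition,
    replicate = experiment$replicate,
    analyte = analyte_def$name,
    area = areas,
    conc_um = conc$conc_um,
    censoring = conc$censoring,
    fmol_per_cell = per_cell_amount(conc$conc_um, experiment$cells_filtered,
                                    experiment$extract_ml,
                                    experiment$dilution),
    mm = intracellular_concentration(
      per_cell_amount(conc$conc_um, experiment$cells_filtered,
                      experiment$extract_ml, experiment$dilution),
      experiment$cell_volume_pl)
  )
}

#' Measure a simulated calibration series
#'
#' Integrates the analyte peak in every calibration run, giving the
#' (concentration, area) points for [fit_calibration()].
#'
#' @param calibration Tibble from [simulate_calibration()].
#' @param analyte_def The analyte the series was generated for.
#' @param tol_ppm XIC tolerance (default 5 ppm).
#' @param rt_halfwidth Integration half-window in minutes (default 0.3).
#' @return A tibble with columns `conc_um`, `replicate`, `area`.
#' @export
measure_calibration <- function(calibration, analyte_def, tol_ppm = 5,
                                rt_halfwidth = 0.3) {
  window <- analyte_def$rt_min + c(-1, 1) * rt_halfwidth
  areas <- purrr::map_dbl(calibration$run, function(run) {
    xic <- extract_xic(run, analyte_def$mz, tol_ppm = tol_ppm)
    max(integrate_peak(xic, window), 0)
  })
  tibble::tibble(conc_um = calibration$conc_um,
                 replicate = calibration$replicate,
                 area = areas)
}
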