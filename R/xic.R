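#' Extract an ion chromatogram
#'
#' Sums, per scan, the intensities of all centroids within a relative m/z
#' window `mz * (1 +/- tol_ppm * 1e-6)` around the target. The default 5 ppm
#' window corresponds to a +/-0.0005% relative tolerance.
#'
#' @param run Centroided run tibble (columns `scan`, `rt_min`, `mz`,
#'   `intensity`), e.g. from [simulate_run()] or [read_mzml()].
#' @param mz Target m/z.
#' @param tol_ppm Relative tolerance in ppm (> 0), default 5.
#'
#' @return A tibble with columns `rt_min` and `intensity`, one row per scan
#'   of the run (zero where no centroid falls in the window).
#' @export
extract_xic <- function(run, mz, tol_ppm = 5) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0", call. = FALSE)
  if (nrow(run) == 0L) stop("empty run", call. = FALSE)
  grid <- attr(run, "scan_times")
  if (is.null(grid)) grid <- sort(unique(run$rt_min))
  lo <- mz * (1 - tol_ppm * 1e-6)
  hi <- mz * (1 + tol_ppm * 1e-6)
  hits <- run[run$mz >= lo & run$mz <= hi, c("rt_min", "intensity")]
  xic <- tibble::tibble(rt_min = grid, intensity = 0)
  if (nrow(hits) > 0L) {
    s <- tapply(hits$intensity, match(hits$rt_min, grid), sum)
    xic$intensity[as.integer(names(s))] <- as.numeric(s)
  }
  xic
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal integral of an ion chromatogram over a retention-time window
#' after baseline subtraction.
#'
#' @param xic XIC tibble from [extract_xic()] (columns `rt_min`,
#'   `intensity`).
#' @param rt_window Length-2 numeric, window in minutes.
#' @param baseline `"linear"` (default) subtracts the straight line between
#'   the window endpoints; `"none"` integrates the raw trace.
#'
#' @return Peak area in intensity x minutes.
#' @export
integrate_peak <- function(xic, rt_window, baseline = c("linear", "none")) {
  baseline <- match.arg(baseline)
  seg <- xic[xic$rt_min >= rt_window[1] & xic$rt_min <= rt_window[2], ]
  if (nrow(seg) < 2L) stop("empty integration window", call. = FALSE)
  y <- seg$intensity
  if (baseline == "linear") {
    y <- y - stats::approx(x = range(seg$rt_min),
                           y = c(y[1], y[length(y)]),
                           xout = seg$rt_min)$y
  }
  pracma::trapz(seg$rt_min, y)
}
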