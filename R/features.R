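#' Detect chromatographic features in a centroided run
#'
#' Centroids are binned into m/z traces by relative-gap clustering (a new
#' trace starts where consecutive sorted m/z values are more than
#' `2 * tol_ppm` apart). Per trace, the baseline level and noise are the
#' median and the median absolute deviation of the trace (off-peak signal
#' dominates both for chromatographic peaks); contiguous segments above
#' baseline + 3 x noise that span at least `min_scans` scans become
#' candidate features, and candidates whose baseline-corrected apex falls
#' below `min_snr` times the noise are dropped. Isolated baseline centroids
#' never span `min_scans` consecutive scans and are thereby rejected.
#'
#' @param run Centroided run tibble.
#' @param min_snr Minimum apex signal-to-noise ratio (default 3). Traces
#'   with zero off-peak signal get infinite S/N.
#' @param min_scans Minimum number of consecutive scans in the peak
#'   (default 5, must be >= 3).
#' @param tol_ppm m/z binning tolerance in ppm (default 5).
#'
#' @return A tibble of features: `mz` (intensity-weighted), `rt_min` (apex),
#'   `area` (trapezoidal), `snr`, `n_scans`, `rt_lo`, `rt_hi`. Empty runs
#'   yield an empty tibble.
#' @export
detect_features <- function(run, min_snr = 3, min_scans = 5, tol_ppm = 5) {
  if (min_snr <= 0) stop("min_snr must be > 0", call. = FALSE)
  if (min_scans < 3) stop("min_scans must be >= 3", call. = FALSE)
  empty <- tibble::tibble(mz = numeric(), rt_min = numeric(),
                          area = numeric(), snr = numeric(),
                          n_scans = integer(), rt_lo = numeric(),
                          rt_hi = numeric())
  if (nrow(run) == 0L) return(empty)
  grid <- attr(run, "scan_times")
  if (is.null(grid)) grid <- sort(unique(run$rt_min))

  d <- dplyr::arrange(run, .data$mz)
  gap <- diff(d$mz) / d$mz[-nrow(d)] * 1e6
  bin <- cumsum(c(1, gap > 2 * tol_ppm))

  feats <- lapply(split(d, bin), function(b) {
    trace <- numeric(length(grid))
    s <- tapply(b$intensity, match(b$rt_min, grid), sum)
    trace[as.integer(names(s))] <- as.numeric(s)
    # baseline level and noise of the trace; for the typical sparse trace
    # (zero off-peak) both are 0 and segments are simply the nonzero scans
    med <- stats::median(trace)
    noise <- stats::mad(trace)
    thr <- med + 3 * noise
    r <- rle(trace > thr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs <- which(r$values & r$lengths >= min_scans)
    if (length(segs) == 0L) return(NULL)
    out <- lapply(segs, function(k) {
      idx <- starts[k]:ends[k]
      apex <- which.max(trace[idx])
      snr <- if (noise == 0) Inf else (max(trace[idx]) - med) / noise
      cen <- b[b$rt_min >= grid[idx[1]] & b$rt_min <= grid[idx[length(idx)]], ]
      tibble::tibble(
        mz = sum(cen$mz * cen$intensity) / sum(cen$intensity),
        rt_min = grid[idx[apex]],
        area = pracma::trapz(grid[idx], trace[idx] - med),
        snr = snr,
        n_scans = length(idx),
        rt_lo = grid[idx[1]],
        rt_hi = grid[idx[length(idx)]]
      )
    })
    dplyr::bind_rows(out)
  })
  feats <- dplyr::bind_rows(feats)
  if (nrow(feats) == 0L) return(empty)
  feats <- feats[feats$snr >= min_snr, ]
  dplyr::arrange(feats, .data$rt_min, .data$mz)
}

.m1_shift <- 1.0033548  # 13C - 12C
# .sulfur_m2_shift() gives the 34S - 32S gap used below

#' Attach isotopologue envelopes to features
#'
#' For every feature, collects co-eluting centroids at +1.00335 Da (M+1) and
#' +1.99580 Da (M+2, the sulfur signature) within `tol_ppm` of the companion
#' m/z, integrates them over the feature's retention window, and reports
#' their areas relative to the feature. Features that are themselves the M+1
#' or M+2 companion of a larger co-eluting feature are marked with
#' `isotopologue = TRUE` so downstream screens can exclude them.
#'
#' @param features Feature tibble from [detect_features()].
#' @param run The run the features came from.
#' @param tol_ppm Companion m/z tolerance in ppm (default 5).
#'
#' @return `features` with added columns `m1_ratio`, `m2_shift` (observed
#'   mean mass shift of the M+2 companion, NA if absent), `m2_ratio`, and
#'   `isotopologue`.
#' @export
attach_isotopologues <- function(features, run, tol_ppm = 5) {
  companions <- function(mz, rt_lo, rt_hi, shift) {
    target <- mz + shift
    lo <- target * (1 - tol_ppm * 1e-6)
    hi <- target * (1 + tol_ppm * 1e-6)
    run[run$mz >= lo & run$mz <= hi &
          run$rt_min >= rt_lo & run$rt_min <= rt_hi, ]
  }
  seg_area <- function(cen) {
    if (nrow(cen) < 2L) return(0)
    s <- dplyr::summarise(dplyr::group_by(cen, .data$rt_min),
                          intensity = sum(.data$intensity))
    if (nrow(s) < 2L) return(0)
    pracma::trapz(s$rt_min, s$intensity)
  }

  n <- nrow(features)
  m1_ratio <- m2_ratio <- numeric(n)
  m2_shift <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    f <- features[i, ]
    c1 <- companions(f$mz, f$rt_lo, f$rt_hi, .m1_shift)
    c2 <- companions(f$mz, f$rt_lo, f$rt_hi, .sulfur_m2_shift())
    m1_ratio[i] <- seg_area(c1) / f$area
    a2 <- seg_area(c2)
    m2_ratio[i] <- a2 / f$area
    if (a2 > 0) {
      m2_shift[i] <- sum(c2$mz * c2$intensity) / sum(c2$intensity) - f$mz
    }
  }
  features$m1_ratio <- m1_ratio
  features$m2_shift <- m2_shift
  features$m2_ratio <- m2_ratio

  # a feature is an envelope member (isotopologue) of another feature when a
  # larger co-eluting feature sits 0.9-4.1 Da below it: this covers the
  # 13C/15N/33S M+1 components, the 34S and 18O/13C2 M+2 components, and the
  # M+3/M+4 tails of intense peaks. Co-eluting distinct compounds within
  # 4 Da of a larger peak are suppressed too -- a documented limitation of
  # the discovery screen, which does no adduct/envelope deconvolution.
  iso <- logical(n)
  for (i in seq_len(n)) {
    delta <- features$mz[i] - features$mz
    hit <- delta >= 0.9 & delta <= 4.1 &
      abs(features$rt_min - features$rt_min[i]) <= 0.1 &
      features$area > features$area[i]
    iso[i] <- any(hit)
  }
  features$isotopologue <- iso
  features
}

#' Flag sulfur-containing features by their M+2 signature
#'
#' A feature is flagged as sulfur-containing when its attached M+2 companion
#' sits at a mass shift of 1.99580 +/- `shift_tol` Da and its relative
#' abundance falls inside `ratio_window` times the expected 34S/32S ratio
#' (0.0447 per sulfur atom). The flag is invariant to overall intensity
#' scaling since it only uses area ratios.
#'
#' @param features Feature tibble with envelopes from
#'   [attach_isotopologues()].
#' @param n_sulfur Assumed number of sulfur atoms (default 1).
#' @param ratio_window Acceptance window as multiples of the expected ratio
#'   (default `c(0.7, 1.3)`).
#' @param shift_tol M+2 mass-shift tolerance in Da (default 0.0005).
#'
#' @return `features` with an added logical column `sulfur_flag`.
#' @export
flag_sulfur <- function(features, n_sulfur = 1, ratio_window = c(0.7, 1.3),
                        shift_tol = 5e-4) {
  if (!all(c("m2_shift", "m2_ratio") %in% names(features))) {
    stop("attach_isotopologues() must be applied first", call. = FALSE)
  }
  expected <- .sulfur_m2_ratio() * n_sulfur
  features$sulfur_flag <- !is.na(features$m2_shift) &
    abs(features$m2_shift - .sulfur_m2_shift()) <= shift_tol &
    features$m2_ratio >= ratio_window[1] * expected &
    features$m2_ratio <= ratio_window[2] * expected
  features
}
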