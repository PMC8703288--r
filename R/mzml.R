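#' Write a run to mzML (centroid mode)
#'
#' Serializes a centroided run tibble to an mzML file through the `mzR`
#' package (Suggests). Scan times are taken from the run's `scan_times`
#' attribute; scans without centroids are written as empty spectra so the
#' time grid survives the round trip.
#'
#' @param run Run tibble from [simulate_run()].
#' @param path Output file path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("writing mzML requires the mzR package", call. = FALSE)
  }
  grid <- attr(run, "scan_times")
  if (is.null(grid)) grid <- sort(unique(run$rt_min))
  n <- length(grid)
  peak_list <- lapply(seq_len(n), function(i) {
    s <- run[run$rt_min == grid[i], ]
    cbind(mz = s$mz, intensity = s$intensity)
  })
  counts <- vapply(peak_list, nrow, integer(1))
  tic <- vapply(peak_list, function(p) sum(p[, 2]), numeric(1))
  bp <- function(p, col) if (nrow(p) == 0L) 0 else p[which.max(p[, 2]), col]
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = counts, totIonCurrent = tic,
    retentionTime = grid * 60,
    basePeakMZ = vapply(peak_list, bp, numeric(1), col = 1),
    basePeakIntensity = vapply(peak_list, bp, numeric(1), col = 2),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(peak_list, function(p) if (nrow(p)) min(p[, 1]) else 0,
                   numeric(1)),
    highMZ = vapply(peak_list, function(p) if (nrow(p)) max(p[, 1]) else 0,
                    numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_
  )
  mzR::writeMSData(peak_list, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read a centroided mzML file as a run tibble
#'
#' @param path mzML file path.
#' @return A run tibble (`scan`, `rt_min`, `mz`, `intensity`) with the
#'   `scan_times` attribute set, directly usable by [extract_xic()] and
#'   [detect_features()].
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package", call. = FALSE)
  }
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h), add = TRUE)
  hdr <- mzR::header(h)
  pk <- mzR::peaks(h)
  if (is.matrix(pk)) pk <- list(pk)
  rows <- purrr::imap(pk, function(p, i) {
    if (nrow(p) == 0L) return(NULL)
    tibble::tibble(scan = i, rt_min = hdr$retentionTime[i] / 60,
                   mz = p[, 1], intensity = p[, 2])
  })
  run <- dplyr::bind_rows(rows)
  attr(run, "scan_times") <- hdr$retentionTime / 60
  attr(run, "sample_id") <- basename(path)
  run
}
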