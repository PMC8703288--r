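#' Define an analyte
#'
#' An analyte couples a molecular formula and adduct (hence an exact m/z and
#' isotope envelope) to a retention time and a detector response factor.
#'
#' @param name Analyte name.
#' @param formula Molecular formula of the neutral molecule (Hill notation).
#' @param adduct_name Adduct, see [adduct()]. Default `"[M+H]+"`.
#' @param rt_min Retention time in minutes.
#' @param response_factor Peak area (intensity x minutes) per uM of analyte
#'   in the injected solution. Must be positive.
#'
#' @return A one-row tibble with columns `name`, `formula`, `adduct`,
#'   `rt_min`, `response_factor`, `mz`.
#' @examples
#' analyte("cysteinolic acid", "C3H9NO4S", rt_min = 9.5,
#'         response_factor = 1.27e7)
#' @export
analyte <- function(name, formula, adduct_name = "[M+H]+", rt_min,
                    response_factor) {
  stopifnot(is.character(name), length(name) == 1L)
  if (response_factor <= 0) stop("response_factor must be > 0", call. = FALSE)
  if (rt_min < 0) stop("rt_min must be >= 0", call. = FALSE)
  comp <- as_formula(formula)
  tibble::tibble(
    name = name,
    formula = format_formula(comp),
    adduct = adduct(adduct_name)$name,
    rt_min = rt_min,
    response_factor = response_factor,
    mz = adduct_mz(comp, adduct_name)
  )
}

#' Simulate a centroided LC-HRMS run
#'
#' Renders each analyte as a Gaussian elution profile at its retention time;
#' every scan inside the peak carries the analyte's full isotope envelope
#' (from [isotope_pattern()]) scaled by the profile. Centroid intensities
#' carry multiplicative log-normal noise with unit mean, and a Poisson number
#' of random baseline centroids is added per scan. With a fixed `seed` the
#' run is bit-identical across calls.
#'
#' The Gaussian amplitude is chosen so that the extracted-ion-chromatogram
#' area of the monoisotopic trace equals `response_factor * amount`.
#'
#' @param analytes Tibble of analytes from [analyte()] (rows may be
#'   concatenated with `dplyr::bind_rows()`).
#' @param amounts Numeric vector of injected concentrations in uM, one per
#'   analyte row (or a single value recycled). All must be >= 0.
#' @param run_length Run duration in minutes (default 18).
#' @param scan_interval Time between scans in seconds (default 0.5).
#' @param peak_sigma Chromatographic peak width (Gaussian sigma) in minutes
#'   (default 0.05).
#' @param noise_cv Within-run technical coefficient of variation applied
#'   multiplicatively to every centroid (default 0.02; 0 disables).
#' @param baseline_rate Mean number of random baseline centroids per scan
#'   (default 2; 0 disables).
#' @param baseline_intensity Median intensity of baseline centroids.
#' @param mz_range m/z acquisition window, default `c(75, 200)`.
#' @param pattern_threshold Relative-abundance cutoff for the simulated
#'   isotope envelope.
#' @param seed Integer seed; `NULL` leaves the RNG state alone (used when a
#'   caller manages seeding).
#' @param sample_id Identifier stored in the run attributes.
#'
#' @return A tibble of centroids with columns `scan`, `rt_min`, `mz`,
#'   `intensity`, carrying attributes `scan_times`, `sample_id` and `seed`.
#' @export
simulate_run <- function(analytes, amounts,
                         run_length = 18, scan_interval = 0.5,
                         peak_sigma = 0.05, noise_cv = 0.02,
                         baseline_rate = 2, baseline_intensity = 1e4,
                         mz_range = c(75, 200),
                         pattern_threshold = 1e-4,
                         seed = NULL, sample_id = "run") {
  if (nrow(analytes) == 0L) stop("empty analyte list", call. = FALSE)
  amounts <- rep_len(amounts, nrow(analytes))
  if (any(amounts < 0)) stop("amounts must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  scan_times <- seq(0, run_length, by = scan_interval / 60)
  rows <- vector("list", nrow(analytes) + 1L)

  for (i in seq_len(nrow(analytes))) {
    a <- analytes[i, ]
    if (amounts[i] == 0) next
    pat <- isotope_pattern(a$formula, threshold = pattern_threshold)
    charge <- adduct(a$adduct)$charge
    mzs <- a$mz + pat$shift / charge
    in_win <- mzs >= mz_range[1] & mzs <= mz_range[2]
    pat <- pat[in_win, ]; mzs <- mzs[in_win]
    idx <- which(abs(scan_times - a$rt_min) <= 4 * peak_sigma)
    if (length(idx) == 0L || nrow(pat) == 0L) next
    amp0 <- a$response_factor * amounts[i] / (peak_sigma * sqrt(2 * pi))
    profile <- amp0 * exp(-(scan_times[idx] - a$rt_min)^2 / (2 * peak_sigma^2))
    rows[[i]] <- tibble::tibble(
      scan = rep(idx, each = nrow(pat)),
      rt_min = rep(scan_times[idx], each = nrow(pat)),
      mz = rep(mzs, times = length(idx)),
      intensity = rep(profile, each = nrow(pat)) *
        rep(pat$abundance, times = length(idx))
    )
  }

  run <- dplyr::bind_rows(rows)
  if (noise_cv > 0 && nrow(run) > 0L) {
    sl <- sqrt(log(1 + noise_cv^2))
    run$intensity <- run$intensity *
      stats::rlnorm(nrow(run), meanlog = -sl^2 / 2, sdlog = sl)
  }
  if (baseline_rate > 0) {
    counts <- stats::rpois(length(scan_times), baseline_rate)
    n <- sum(counts)
    if (n > 0L) {
      sidx <- rep(seq_along(scan_times), counts)
      run <- dplyr::bind_rows(run, tibble::tibble(
        scan = sidx,
        rt_min = scan_times[sidx],
        mz = stats::runif(n, mz_range[1], mz_range[2]),
        intensity = stats::rlnorm(n, meanlog = log(baseline_intensity),
                                  sdlog = 1)
      ))
    }
  }
  run <- dplyr::arrange(run, .data$scan, .data$mz)
  attr(run, "scan_times") <- scan_times
  attr(run, "sample_id") <- sample_id
  attr(run, "seed") <- seed
  run
}

#' Simulate a calibration dilution series
#'
#' One run per concentration level and replicate, each containing a single
#' analyte at the stated concentration.
#'
#' @param analyte_def One-row analyte tibble from [analyte()].
#' @param levels_um Strictly positive, distinct concentration levels in uM.
#' @param replicates Replicates per level (default 3).
#' @param seed Integer seed for the whole series.
#' @param ... Passed to [simulate_run()] (noise, scan settings, ...).
#'
#' @return A tibble with columns `conc_um`, `replicate` and a list-column
#'   `run` of simulated runs.
#' @export
simulate_calibration <- function(analyte_def, levels_um, replicates = 3,
                                 seed = 1, ...) {
  if (any(levels_um <= 0)) stop("levels must be > 0", call. = FALSE)
  if (anyDuplicated(levels_um)) stop("levels must be distinct", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  set.seed(seed)
  design <- tidyr::expand_grid(conc_um = sort(levels_um),
                               replicate = seq_len(replicates))
  design$run <- purrr::map2(design$conc_um, design$replicate, function(c, r) {
    simulate_run(analyte_def, c, seed = NULL,
                 sample_id = sprintf("cal_%g_%d", c, r), ...)
  })
  design
}

# per-cell amount (fmol/cell) -> concentration in the injected solution (uM)
# 1 uM in 1 mL = 1e6 fmol
.fmol_per_cell_to_um <- function(fmol_per_cell, cells, extract_ml, dilution) {
  fmol_per_cell * cells / 1e6 / extract_ml / dilution
}

#' Simulate a multi-condition culture experiment
#'
#' For every condition and biological replicate, the configured true per-cell
#' amounts are jittered by the biological coefficient of variation (unit-mean
#' log-normal), converted to injected-solution concentrations via
#' `fmol/cell x cells filtered / extract volume / dilution`, and rendered as
#' a centroided run with [simulate_run()]. The returned metadata carries the
#' jittered true values so recovery can be tested against ground truth.
#'
#' @param scenario A scenario from [scenario()] or one of the packaged
#'   constructors (e.g. [scenario_tw_xenic()]).
#' @param seed Integer seed; overrides the scenario's stored seed.
#'
#' @return A tibble with one row per sample: `sample_id`, `condition`,
#'   `replicate`, `cells_filtered`, `extract_ml`, `dilution`,
#'   `cell_volume_pl`, a list-column `truth` (per-analyte tibble with
#'   `analyte`, `true_fmol_per_cell`, `conc_um`) and a list-column `run`.
#' @export
simulate_experiment <- function(scenario, seed = scenario$seed) {
  sc <- validate_scenario(scenario)
  set.seed(seed)
  cells <- sc$cell_density_per_ml * sc$culture_ml
  conds <- unique(sc$conditions$condition)
  samples <- tidyr::expand_grid(condition = conds,
                                replicate = seq_len(sc$replicates))
  sl <- sqrt(log(1 + sc$biological_cv^2))

  out <- purrr::pmap(samples, function(condition, replicate) {
    truth <- sc$conditions[sc$conditions$condition == condition, ]
    truth <- truth[match(sc$analytes$name, truth$analyte), ]
    jitter <- if (sc$biological_cv > 0) {
      stats::rlnorm(nrow(truth), meanlog = -sl^2 / 2, sdlog = sl)
    } else rep(1, nrow(truth))
    true_fmol <- truth$fmol_per_cell * jitter
    conc <- .fmol_per_cell_to_um(true_fmol, cells, sc$extract_ml, sc$dilution)
    id <- sprintf("%s_%s_r%d", gsub("[^A-Za-z0-9]+", "-", sc$species),
                  gsub("[^A-Za-z0-9]+", "-", condition), replicate)
    run <- rlang::exec(simulate_run, analytes = sc$analytes, amounts = conc,
                       seed = NULL, sample_id = id, !!!sc$run_args)
    tibble::tibble(
      sample_id = id, condition = condition, replicate = replicate,
      cells_filtered = cells, extract_ml = sc$extract_ml,
      dilution = sc$dilution, cell_volume_pl = sc$cell_volume_pl,
      truth = list(tibble::tibble(analyte = truth$analyte,
                                  true_fmol_per_cell = true_fmol,
                                  conc_um = conc)),
      run = list(run)
    )
  })
  dplyr::bind_rows(out)
}
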