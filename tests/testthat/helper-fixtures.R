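# Short-run fixtures: 4-minute runs with the analyte eluting at 2 min keep
# simulation-heavy tests fast while exercising the same code paths as the
# full 18-minute defaults.

short_cys <- function(rt_min = 2) {
  analyte("cysteinolic acid", "C3H9NO4S", "[M+H]+", rt_min = rt_min,
          response_factor = 1.27e7)
}

short_gbt <- function(rt_min = 1) {
  analyte("glycine betaine", "C5H11NO2", "[M+H]+", rt_min = rt_min,
          response_factor = 1.59e8)
}

short_run <- function(analytes = short_cys(), amounts = 10, seed = 1, ...) {
  simulate_run(analytes, amounts, run_length = 4, seed = seed, ...)
}

# hand-built centroided run on a regular grid: `traces` is a list of
# list(mz =, intensity = vector over the grid)
manual_run <- function(traces, rt = seq(0, 4, by = 1 / 120)) {
  rows <- lapply(traces, function(tr) {
    keep <- tr$intensity > 0
    tibble::tibble(scan = seq_along(rt)[keep], rt_min = rt[keep],
                   mz = tr$mz, intensity = tr$intensity[keep])
  })
  run <- dplyr::arrange(dplyr::bind_rows(rows), scan, mz)
  attr(run, "scan_times") <- rt
  run
}

gaussian_trace <- function(rt, center, sigma, amplitude) {
  amplitude * exp(-(rt - center)^2 / (2 * sigma^2))
}
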