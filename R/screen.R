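#' Screen for salinity-up-regulated features
#'
#' Matches features across replicate runs of two conditions (greedy
#' nearest-neighbour matching within `tol_ppm` in m/z and `rt_tol` minutes
#' in retention time, seeded from the most intense features), then selects
#' candidates whose mean area under the high condition exceeds the low
#' condition by at least `fc_min`-fold with a two-sided Welch t-test p-value
#' at or below `p_max`. Features absent from a replicate contribute zero
#' area. Isotopologue companion features (see [attach_isotopologues()]) are
#' excluded before matching. The Welch test is a screening heuristic, not a
#' corrected inference: candidate lists carry raw p-values.
#'
#' @param features_low,features_high Lists of per-replicate feature tibbles
#'   (from [detect_features()], optionally with envelopes and sulfur flags).
#' @param fc_min Minimum fold change `mean(high)/mean(low)` (default 1.5).
#' @param p_max Maximum Welch p-value (default 0.05). With fewer than 2
#'   replicates per condition the test is skipped and `p_value` is `NA`
#'   (flagged in `test_skipped`); the same happens for exactly constant
#'   areas, where the statistic is undefined.
#' @param tol_ppm m/z matching tolerance (default 5 ppm).
#' @param rt_tol Retention-time matching tolerance in minutes (default 0.3).
#'
#' @return A tibble of candidates sorted by decreasing fold change, with
#'   columns `mz`, `rt_min`, `mean_low`, `mean_high`, `fold_change`,
#'   `p_value`, `test_skipped`, `sulfur_flag`, `m2_ratio`.
#' @export
differential_screen <- function(features_low, features_high, fc_min = 1.5,
                                p_max = 0.05, tol_ppm = 5, rt_tol = 0.3) {
  if (inherits(features_low, "data.frame")) features_low <- list(features_low)
  if (inherits(features_high, "data.frame")) features_high <- list(features_high)
  n_low <- length(features_low)
  n_high <- length(features_high)

  tag <- function(lst, condition) {
    purrr::imap(lst, function(f, i) {
      if (nrow(f) == 0L) return(NULL)
      f$condition <- condition
      f$replicate <- i
      f
    })
  }
  all <- dplyr::bind_rows(c(tag(features_low, "low"), tag(features_high, "high")))
  if (nrow(all) == 0L) {
    return(tibble::tibble(mz = numeric(), rt_min = numeric(),
                          mean_low = numeric(), mean_high = numeric(),
                          fold_change = numeric(), p_value = numeric(),
                          test_skipped = logical(), sulfur_flag = logical(),
                          m2_ratio = numeric()))
  }
  if ("isotopologue" %in% names(all)) all <- all[!all$isotopologue, ]

  # greedy clustering seeded from the most intense features
  all <- dplyr::arrange(all, dplyr::desc(.data$area))
  cl_mz <- cl_rt <- numeric(0)
  cluster <- integer(nrow(all))
  for (i in seq_len(nrow(all))) {
    if (length(cl_mz) > 0L) {
      ok <- abs(all$mz[i] - cl_mz) <= cl_mz * tol_ppm * 1e-6 &
        abs(all$rt_min[i] - cl_rt) <= rt_tol
    } else ok <- logical(0)
    if (any(ok)) {
      cluster[i] <- which(ok)[1]
    } else {
      cl_mz <- c(cl_mz, all$mz[i])
      cl_rt <- c(cl_rt, all$rt_min[i])
      cluster[i] <- length(cl_mz)
    }
  }
  all$cluster <- cluster

  welch_p <- function(x, y) {
    if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(NA_real_)
    tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
  }

  out <- lapply(split(all, all$cluster), function(g) {
    lows <- highs <- numeric(0)
    lows <- g$area[g$condition == "low"][
      match(seq_len(n_low), g$replicate[g$condition == "low"])]
    highs <- g$area[g$condition == "high"][
      match(seq_len(n_high), g$replicate[g$condition == "high"])]
    lows[is.na(lows)] <- 0
    highs[is.na(highs)] <- 0
    p <- welch_p(highs, lows)
    tibble::tibble(
      mz = mean(g$mz),
      rt_min = mean(g$rt_min),
      mean_low = mean(lows),
      mean_high = mean(highs),
      fold_change = mean(highs) / mean(lows),
      p_value = p,
      test_skipped = is.na(p),
      sulfur_flag = if ("sulfur_flag" %in% names(g)) {
        mean(g$sulfur_flag) > 0.5
      } else NA,
      m2_ratio = if ("m2_ratio" %in% names(g)) mean(g$m2_ratio) else NA_real_
    )
  })
  out <- dplyr::bind_rows(out)
  cand <- out[out$fold_change >= fc_min &
                (out$test_skipped | out$p_value <= p_max), ]
  dplyr::arrange(cand, dplyr::desc(.data$fold_change))
}
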