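#' Neutral-loss library
#'
#' `neutral_loss()` builds one library entry; `default_neutral_losses()`
#' returns the standard small-molecule losses used for sulfonate MS/MS
#' annotation: water, ammonia, carbon dioxide, sulfur trioxide and sulfurous
#' acid. Losing water plus sulfurous acid together is how the sulfonic group
#' leaves protonated cysteinolic acid, yielding the C3H6N+ ion.
#'
#' @param name Loss label.
#' @param formula Molecular formula of the lost neutral.
#' @return A one-row tibble with `name`, `formula`, `mass`.
#' @export
neutral_loss <- function(name, formula) {
  comp <- as_formula(formula)
  m <- monoisotopic_mass(comp)
  if (m <= 0) stop("neutral loss must have positive mass", call. = FALSE)
  tibble::tibble(name = name, formula = format_formula(comp), mass = m)
}

#' @rdname neutral_loss
#' @export
default_neutral_losses <- function() {
  dplyr::bind_rows(
    neutral_loss("H2O", "H2O"),
    neutral_loss("NH3", "NH3"),
    neutral_loss("CO2", "CO2"),
    neutral_loss("SO3", "SO3"),
    neutral_loss("H2SO3", "H2SO3")
  )
}

# multisets of 0..max_n indices drawn from 1..n (combinations with repetition)
.loss_combinations <- function(n, max_n) {
  out <- list(integer(0))
  if (max_n >= 1) out <- c(out, as.list(seq_len(n)))
  k <- 2
  while (k <= max_n) {
    prev <- out[lengths(out) == k - 1]
    for (p in prev) {
      last <- p[length(p)]
      for (j in last:n) out <- c(out, list(c(p, j)))
    }
    k <- k + 1
  }
  out
}

#' Annotate MS/MS fragments by neutral-loss combinations
#'
#' Enumerates all combinations (with repetition, up to `max_losses`) of
#' library losses whose summed formula is element-wise subtractable from the
#' protonated precursor, and assigns each observed fragment to the
#' combination minimising the absolute ppm error within `tol_ppm`. Ties are
#' broken by fewer losses, then by lower absolute error. The empty
#' combination allows the precursor ion itself to be assigned.
#'
#' The default tolerance is 10 ppm rather than the 5 ppm MS1 convention:
#' low-m/z fragment ions in tandem spectra routinely carry several ppm of
#' calibration error beyond survey-scan accuracy.
#'
#' @param peaks Numeric vector of observed fragment m/z values, or a data
#'   frame with an `mz` column.
#' @param precursor Formula (string or `formula_comp`) of the neutral
#'   precursor molecule.
#' @param adduct_name Precursor adduct (default `"[M+H]+"`).
#' @param losses Loss library tibble (default [default_neutral_losses()]).
#' @param tol_ppm Assignment tolerance in ppm (default 10).
#' @param max_losses Maximum number of combined losses (default 2).
#'
#' @return A tibble with one row per observed peak: `mz`, `assigned`,
#'   `loss` (e.g. `"H2O+H2SO3"`, `""` for the intact precursor, `NA` when
#'   unassigned), `fragment_formula` (of the ion), `theoretical_mz`,
#'   `error_ppm`, `n_losses`.
#' @examples
#' annotate_fragments(c(156.03232, 138.02196, 56.04979), "C3H9NO4S")
#' @export
annotate_fragments <- function(peaks, precursor, adduct_name = "[M+H]+",
                               losses = default_neutral_losses(),
                               tol_ppm = 10, max_losses = 2) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0", call. = FALSE)
  if (max_losses < 1) stop("max_losses must be >= 1", call. = FALSE)
  if (is.data.frame(peaks)) peaks <- peaks$mz
  empty <- tibble::tibble(mz = numeric(), assigned = logical(),
                          loss = character(), fragment_formula = character(),
                          theoretical_mz = numeric(), error_ppm = numeric(),
                          n_losses = integer())
  if (length(peaks) == 0L) return(empty)

  comp <- as_formula(precursor)
  ad <- adduct(adduct_name)
  # ion composition: precursor plus the adduct proton (for subtractability)
  ion_comp <- if (ad$name == "[M+H]+") formula_add(comp, "H") else comp
  prec_mz <- adduct_mz(comp, adduct_name)

  combos <- .loss_combinations(nrow(losses), max_losses)
  cand <- purrr::map(combos, function(idx) {
    total <- Reduce(formula_add,
                    lapply(idx, function(j) as_formula(losses$formula[j])),
                    new_formula_comp(integer(0)))
    frag <- tryCatch(formula_subtract(ion_comp, total), error = function(e) NULL)
    if (is.null(frag)) return(NULL)
    tibble::tibble(
      loss = paste(losses$name[idx], collapse = "+"),
      fragment_formula = format_formula(frag),
      theoretical_mz = prec_mz - monoisotopic_mass(total),
      n_losses = length(idx)
    )
  })
  cand <- dplyr::bind_rows(cand)
  cand <- cand[cand$theoretical_mz > 0, ]

  out <- lapply(peaks, function(p) {
    err <- mass_error_ppm(p, cand$theoretical_mz)
    ok <- which(abs(err) <= tol_ppm)
    if (length(ok) == 0L) {
      return(tibble::tibble(mz = p, assigned = FALSE, loss = NA_character_,
                            fragment_formula = NA_character_,
                            theoretical_mz = NA_real_, error_ppm = NA_real_,
                            n_losses = NA_integer_))
    }
    # minimise |ppm error|; exact ties (e.g. identical theoretical masses)
    # broken by fewer losses
    best <- ok[order(round(abs(err[ok]), 6), cand$n_losses[ok])][1]
    tibble::tibble(mz = p, assigned = TRUE, loss = cand$loss[best],
                   fragment_formula = cand$fragment_formula[best],
                   theoretical_mz = cand$theoretical_mz[best],
                   error_ppm = err[best], n_losses = cand$n_losses[best])
  })
  dplyr::bind_rows(out)
}
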