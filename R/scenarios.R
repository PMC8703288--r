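#' Build a culture-experiment scenario
#'
#' A scenario bundles the "wet-lab" side of a simulated experiment: which
#' analytes are present, the true per-cell amounts under each condition, the
#' biological variability, and the harvest/extraction context that links
#' per-cell amounts to concentrations in the injected solution.
#'
#' @param species Species label.
#' @param analytes Analyte tibble ([analyte()] rows).
#' @param conditions Tibble with columns `condition`, `analyte`,
#'   `fmol_per_cell` giving the true per-cell amount of each analyte under
#'   each condition. Every condition must cover the same analyte set.
#' @param replicates Biological replicates per condition (default 3).
#' @param biological_cv Between-replicate coefficient of variation of the
#'   true per-cell amounts (default 0.10).
#' @param cell_density_per_ml Culture cell density at harvest (cells/mL).
#' @param culture_ml Culture volume filtered (mL, default 30).
#' @param extract_ml Extract volume (mL, default 1: two 500-uL methanol
#'   additions).
#' @param dilution Dilution factor of the extract before injection
#'   (default 3: 50 uL extract + 100 uL diluent).
#' @param cell_volume_pl Cell volume in pL, used to convert per-cell amounts
#'   to intracellular molarity.
#' @param seed Default seed used by [simulate_experiment()].
#' @param ... Additional arguments stored for [simulate_run()] (e.g.
#'   `noise_cv`, `run_length`, `baseline_rate`).
#'
#' @return A list of class `"osmoquant_scenario"`.
#' @export
scenario <- function(species, analytes, conditions, replicates = 3,
                     biological_cv = 0.10, cell_density_per_ml = 1e5,
                     culture_ml = 30, extract_ml = 1, dilution = 3,
                     cell_volume_pl = 1, seed = 1, ...) {
  sc <- structure(list(
    species = species, analytes = analytes, conditions = conditions,
    replicates = as.integer(replicates), biological_cv = biological_cv,
    cell_density_per_ml = cell_density_per_ml, culture_ml = culture_ml,
    extract_ml = extract_ml, dilution = dilution,
    cell_volume_pl = cell_volume_pl, seed = seed,
    run_args = list(...)
  ), class = "osmoquant_scenario")
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  if (!inherits(sc, "osmoquant_scenario")) {
    stop("not a scenario object; see scenario()", call. = FALSE)
  }
  if (sc$replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (sc$biological_cv < 0) stop("biological_cv must be >= 0", call. = FALSE)
  vols <- c(cell_density_per_ml = sc$cell_density_per_ml,
            culture_ml = sc$culture_ml, extract_ml = sc$extract_ml,
            dilution = sc$dilution, cell_volume_pl = sc$cell_volume_pl)
  if (any(vols <= 0)) {
    stop("scenario fields must be > 0: ",
         paste(names(vols)[vols <= 0], collapse = ", "), call. = FALSE)
  }
  sets <- split(sc$conditions$analyte, sc$conditions$condition)
  ok <- vapply(sets, function(s) setequal(s, sc$analytes$name), logical(1))
  if (!all(ok)) {
    stop("conditions must all cover the same analyte set as `analytes`",
         call. = FALSE)
  }
  sc
}

#' @export
print.osmoquant_scenario <- function(x, ...) {
  cat("<scenario>", x$species, "\n",
      length(unique(x$conditions$condition)), "condition(s) x",
      x$replicates, "replicate(s);",
      nrow(x$analytes), "analyte(s); biological CV",
      x$biological_cv, "\n")
  invisible(x)
}

#' Cysteinolic acid analyte definition
#'
#' Cysteinolic acid (2-amino-3-hydroxy-1-propanesulfonic acid, C3H9NO4S),
#' observed as the protonated ion at m/z 156.0325, with the external
#' calibration response of 1.27e7 area units per uM and a late HILIC
#' retention time.
#'
#' @param rt_min Retention time (default 9.5 min).
#' @return One-row analyte tibble.
#' @export
cysteinolic_acid <- function(rt_min = 9.5) {
  analyte("cysteinolic acid", "C3H9NO4S", "[M+H]+", rt_min = rt_min,
          response_factor = 1.27e7)
}

#' Zwitterionic osmolyte panel
#'
#' The co-monitored osmolytes glycine betaine, homarine, ectoine and DMSP,
#' with response factors set to their published calibration slopes and
#' retention times staggered across the HILIC gradient.
#'
#' @return Analyte tibble (4 rows).
#' @export
osmolyte_panel <- function() {
  dplyr::bind_rows(
    analyte("DMSP", "C5H10O2S", "[M+H]+", rt_min = 6.5,
            response_factor = 8.28e7),
    analyte("homarine", "C7H7NO2", "[M+H]+", rt_min = 7.0,
            response_factor = 5.26e8),
    analyte("glycine betaine", "C5H11NO2", "[M+H]+", rt_min = 8.0,
            response_factor = 1.59e8),
    analyte("ectoine", "C6H10N2O2", "[M+H]+", rt_min = 8.8,
            response_factor = 2.96e8)
  )
}

.salinity_conditions <- function(base_fmol, short_fold, long_fold) {
  tibble::tibble(
    condition = c("35 PSU", "50 PSU 24 h", "50 PSU"),
    analyte = "cysteinolic acid",
    fmol_per_cell = base_fmol * c(1, short_fold, long_fold)
  )
}

#' Packaged salinity-stress scenarios for Thalassiosira weissflogii
#'
#' Three-condition salinity experiments (constant 35 PSU; transfer to 50 PSU
#' sampled after 24 h; two generations at 50 PSU) with N = 3 biological
#' replicates and 10% biological CV. The xenic baseline per-cell amount is
#' 22.3 fmol/cell; short- and long-term stress scale it by 2.0x and 2.4x.
#' The axenic baseline is 1.5x the xenic one, with 1.1x (not significant)
#' and 2.6x under short- and long-term stress. The cell volume of 2.7875 pL
#' makes the baseline intracellular concentration 8.0 mM.
#'
#' @param biological_cv Biological CV (default 0.10).
#' @param seed Default seed.
#' @return A scenario object.
#' @export
scenario_tw_xenic <- function(biological_cv = 0.10, seed = 1) {
  scenario("Thalassiosira weissflogii (xenic)",
           analytes = cysteinolic_acid(),
           conditions = .salinity_conditions(22.3, 2.0, 2.4),
           replicates = 3, biological_cv = biological_cv,
           cell_density_per_ml = 1e5, cell_volume_pl = 2.7875, seed = seed)
}

#' @rdname scenario_tw_xenic
#' @export
scenario_tw_axenic <- function(biological_cv = 0.10, seed = 1) {
  scenario("Thalassiosira weissflogii (axenic)",
           analytes = cysteinolic_acid(),
           conditions = .salinity_conditions(22.3 * 1.5, 1.1, 2.6),
           replicates = 3, biological_cv = biological_cv,
           cell_density_per_ml = 1e5, cell_volume_pl = 2.7875, seed = seed)
}

#' Packaged Prorocentrum minimum survey fixture
#'
#' Single-condition (35 PSU) culture of the dinoflagellate P. minimum with a
#' true cysteinolic acid content of 50.6 fmol/cell and a cell volume of
#' 0.7116 pL, so the true intracellular concentration is 71.1 mM.
#'
#' @param biological_cv Biological CV (default 0.10).
#' @param seed Default seed.
#' @return A scenario object.
#' @export
scenario_p_minimum <- function(biological_cv = 0.10, seed = 1) {
  scenario("Prorocentrum minimum",
           analytes = cysteinolic_acid(),
           conditions = tibble::tibble(condition = "35 PSU",
                                       analyte = "cysteinolic acid",
                                       fmol_per_cell = 50.6),
           replicates = 3, biological_cv = biological_cv,
           cell_density_per_ml = 5e4, cell_volume_pl = 0.7116, seed = seed)
}

#' Packaged salinity-mining fixture
#'
#' Two-condition (35 vs 50 PSU) T. weissflogii experiment carrying the full
#' osmolyte panel plus cysteinolic acid, in which only cysteinolic acid is
#' up-regulated (2.4x) under elevated salinity. Used to exercise the
#' discovery screen: the only up-regulated, sulfur-flagged feature should be
#' the cysteinolic acid ion.
#'
#' @param biological_cv Biological CV (default 0.05).
#' @param seed Default seed.
#' @return A scenario object.
#' @export
scenario_salinity_screen <- function(biological_cv = 0.05, seed = 1) {
  panel <- dplyr::bind_rows(osmolyte_panel(), cysteinolic_acid())
  base <- tibble::tibble(
    condition = "35 PSU",
    analyte = panel$name,
    fmol_per_cell = c(0.5, 35.4, 234.7, 85.2, 22.3)
  )
  high <- base
  high$condition <- "50 PSU"
  high$fmol_per_cell[high$analyte == "cysteinolic acid"] <- 22.3 * 2.4
  scenario("Thalassiosira weissflogii (xenic)",
           analytes = panel,
           conditions = dplyr::bind_rows(base, high),
           replicates = 3, biological_cv = biological_cv,
           cell_density_per_ml = 1e5, cell_volume_pl = 2.7875, seed = seed)
}
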