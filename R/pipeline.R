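#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow in one place so that a
#' run is fully described by (config, seed). Defaults mirror the package
#' conventions: 5 ppm mass tolerance, 0.3 min retention-time matching,
#' fold-change cutoff 1.5, Welch p cutoff 0.05, through-origin calibration
#' with ICH limits.
#'
#' @param scenario A scenario object ([scenario()]) or one of the packaged
#'   names `"tw_xenic"`, `"tw_axenic"`, `"p_minimum"`, `"salinity_screen"`.
#' @param target_analyte Name of the analyte to quantify (must be in the
#'   scenario's analyte table).
#' @param calibration_levels_um Calibration concentrations in uM.
#' @param calibration_replicates Replicates per level (default 3).
#' @param tol_ppm Mass tolerance in ppm.
#' @param rt_tol Retention-time matching tolerance in minutes.
#' @param fc_min,p_max Screening cutoffs, see [differential_screen()].
#' @param screen_conditions Length-2 character vector (reference, treatment)
#'   for the differential screen; default: first and last scenario
#'   condition. Ignored for single-condition scenarios.
#' @param msms_peaks Optional numeric vector of MS/MS fragment m/z values to
#'   annotate against the target analyte's formula.
#' @param seed Default seed.
#' @return A named list of class `"osmoquant_config"`.
#' @export
pipeline_config <- function(scenario = "tw_xenic",
                            target_analyte = "cysteinolic acid",
                            calibration_levels_um = c(2, 5, 10, 25, 50, 100),
                            calibration_replicates = 3,
                            tol_ppm = 5, rt_tol = 0.3,
                            fc_min = 1.5, p_max = 0.05,
                            screen_conditions = NULL,
                            msms_peaks = NULL,
                            seed = 1) {
  cfg <- structure(list(
    scenario = scenario, target_analyte = target_analyte,
    calibration_levels_um = calibration_levels_um,
    calibration_replicates = calibration_replicates,
    tol_ppm = tol_ppm, rt_tol = rt_tol, fc_min = fc_min, p_max = p_max,
    screen_conditions = screen_conditions, msms_peaks = msms_peaks,
    seed = seed
  ), class = "osmoquant_config")
  validate_config(cfg)
}

.resolve_scenario <- function(x) {
  if (inherits(x, "osmoquant_scenario")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(switch(x,
      tw_xenic = scenario_tw_xenic(),
      tw_axenic = scenario_tw_axenic(),
      p_minimum = scenario_p_minimum(),
      salinity_screen = scenario_salinity_screen(),
      stop("config field `scenario`: unknown packaged scenario '", x, "'",
           call. = FALSE)
    ))
  }
  stop("config field `scenario`: must be a scenario object or packaged name",
       call. = FALSE)
}

validate_config <- function(cfg) {
  sc <- .resolve_scenario(cfg$scenario)
  problems <- character(0)
  if (!cfg$target_analyte %in% sc$analytes$name) {
    problems <- c(problems, sprintf(
      "target_analyte: '%s' is not among the scenario analytes (%s)",
      cfg$target_analyte, paste(sc$analytes$name, collapse = ", ")))
  }
  if (any(cfg$calibration_levels_um <= 0)) {
    problems <- c(problems, "calibration_levels_um: levels must be > 0")
  }
  if (cfg$tol_ppm <= 0) problems <- c(problems, "tol_ppm: must be > 0")
  if (cfg$rt_tol <= 0) problems <- c(problems, "rt_tol: must be > 0")
  if (cfg$fc_min <= 0) problems <- c(problems, "fc_min: must be > 0")
  if (cfg$p_max <= 0 || cfg$p_max > 1) {
    problems <- c(problems, "p_max: must be in (0, 1]")
  }
  if (!is.null(cfg$screen_conditions)) {
    bad <- setdiff(cfg$screen_conditions, unique(sc$conditions$condition))
    if (length(cfg$screen_conditions) != 2L || length(bad) > 0L) {
      problems <- c(problems, paste0(
        "screen_conditions: must name two scenario conditions",
        if (length(bad)) paste0(" (unknown: ", paste(bad, collapse = ", "), ")")))
    }
  }
  if (length(problems) > 0L) {
    stop("invalid pipeline configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Reads a human-editable YAML file whose keys match the arguments of
#' [pipeline_config()] (with `scenario` as a packaged scenario name).
#'
#' @param path YAML file path.
#' @return A validated configuration.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("config field `path`: file does not exist: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), allowed)
  if (length(extra) > 0L) {
    stop("unknown config field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  rlang::exec(pipeline_config, !!!raw)
}

.stage_msg <- function(stage, t0) {
  message(sprintf("[%s] done in %.2f s", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full screening and quantification pipeline
#'
#' Executes simulate -> screen -> annotate -> quantify -> stats on a
#' configuration, optionally writing the stage tables (features, screening
#' candidates, quantification, condition comparisons) as tab-separated files
#' plus a machine-readable JSON summary. Identical (config, seed) pairs
#' produce byte-identical outputs; progress is logged to stderr.
#'
#' @param config Configuration from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param seed Seed for all randomness (default: the config's seed).
#' @return A list with `experiment`, `features`, `candidates`,
#'   `annotations`, `calibration`, `quant`, `summary`, `comparisons`, and
#'   `summary_json` (the summary as a list).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = config$seed) {
  config <- validate_config(config)
  sc <- .resolve_scenario(config$scenario)
  target <- sc$analytes[sc$analytes$name == config$target_analyte, ]

  t0 <- as.numeric(Sys.time())
  experiment <- simulate_experiment(sc, seed = seed)
  cal_runs <- simulate_calibration(target, config$calibration_levels_um,
                                   replicates = config$calibration_replicates,
                                   seed = seed + 1L)
  .stage_msg("simulate", t0)

  t0 <- as.numeric(Sys.time())
  feats <- purrr::map(experiment$run, function(run) {
    f <- detect_features(run, tol_ppm = config$tol_ppm)
    f <- attach_isotopologues(f, run, tol_ppm = config$tol_ppm)
    flag_sulfur(f)
  })
  features <- dplyr::bind_rows(
    purrr::map2(feats, experiment$sample_id,
                function(f, id) dplyr::mutate(f, sample_id = id)))
  conds <- unique(experiment$condition)
  candidates <- NULL
  if (length(conds) >= 2L) {
    pair <- config$screen_conditions %||% c(conds[1], conds[length(conds)])
    candidates <- differential_screen(
      feats[experiment$condition == pair[1]],
      feats[experiment$condition == pair[2]],
      fc_min = config$fc_min, p_max = config$p_max,
      tol_ppm = config$tol_ppm, rt_tol = config$rt_tol)
  }
  .stage_msg("screen", t0)

  t0 <- as.numeric(Sys.time())
  annotations <- NULL
  if (!is.null(config$msms_peaks)) {
    annotations <- annotate_fragments(config$msms_peaks, target$formula)
  }
  .stage_msg("annotate", t0)

  t0 <- as.numeric(Sys.time())
  cal_points <- measure_calibration(cal_runs, target,
                                    tol_ppm = config$tol_ppm)
  fit <- fit_calibration(cal_points, analyte_name = target$name)
  quant <- quantify_samples(experiment, target, fit,
                            tol_ppm = config$tol_ppm)
  .stage_msg("quantify", t0)

  t0 <- as.numeric(Sys.time())
  comparisons <- NULL
  if (length(conds) >= 2L && all(table(quant$condition) >= 2L)) {
    comparisons <- compare_conditions(quant, reference = conds[1])
  }
  summary_tbl <- dplyr::summarise(
    dplyr::group_by(quant, .data$condition),
    mean_fmol_per_cell = mean(.data$fmol_per_cell),
    sd_fmol_per_cell = stats::sd(.data$fmol_per_cell),
    mean_mm = mean(.data$mm),
    sd_mm = stats::sd(.data$mm),
    n = dplyr::n(), .groups = "drop")
  .stage_msg("stats", t0)

  cfg_plain <- unclass(config)
  cfg_plain$scenario <- if (is.character(config$scenario)) {
    config$scenario
  } else sc$species
  summary_json <- list(
    package = "osmoquant",
    version = as.character(utils::packageVersion("osmoquant")),
    seed = seed,
    config = cfg_plain,
    config_hash = rlang::hash(cfg_plain),
    species = sc$species,
    calibration = as.list(glance(fit)),
    conditions = summary_tbl,
    fold_changes = if (!is.null(comparisons)) {
      comparisons$comparisons[, c("group1", "group2", "fold_change",
                                  "p_adj", "significance")]
    },
    n_candidates = if (!is.null(candidates)) nrow(candidates)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(features, file.path(out_dir, "features.tsv"))
    if (!is.null(candidates)) {
      readr::write_tsv(candidates, file.path(out_dir, "candidates.tsv"))
    }
    if (!is.null(annotations)) {
      readr::write_tsv(annotations, file.path(out_dir, "annotations.tsv"))
    }
    readr::write_tsv(quant, file.path(out_dir, "quantification.tsv"))
    readr::write_tsv(summary_tbl, file.path(out_dir, "condition_summary.tsv"))
    if (!is.null(comparisons)) {
      readr::write_tsv(comparisons$comparisons,
                       file.path(out_dir, "comparisons.tsv"))
    }
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }

  invisible(list(experiment = experiment, features = features,
                 candidates = candidates, annotations = annotations,
                 calibration = fit, quant = quant, summary = summary_tbl,
                 comparisons = comparisons, summary_json = summary_json))
}
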