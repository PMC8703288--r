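#' Fold change between condition means
#'
#' @param reference,treatment Numeric vectors of replicate values (e.g.
#'   fmol/cell). The reference mean must be positive.
#' @return `mean(treatment) / mean(reference)`.
#' @export
fold_change <- function(reference, treatment) {
  m <- mean(reference)
  if (!is.finite(m) || m <= 0) {
    stop("reference mean must be > 0", call. = FALSE)
  }
  mean(treatment) / m
}

.get_groups <- function(data, value, group) {
  value <- rlang::ensym(value)
  group <- rlang::ensym(group)
  v <- rlang::eval_tidy(value, data)
  g <- factor(rlang::eval_tidy(group, data))
  if (any(is.na(v)) || any(is.na(g))) stop("missing values", call. = FALSE)
  list(value = v, group = g)
}

#' One-way analysis of variance
#'
#' Classical between/within sums-of-squares decomposition via
#' [stats::aov()]. Requires at least two groups with at least two values
#' each. When every observation is identical the F statistic is undefined;
#' the function then returns `p = 1` with a warning.
#'
#' @param data Data frame of replicate measurements.
#' @param value,group Columns (unquoted) holding the measurement and the
#'   condition label.
#' @return A one-row tibble: `f`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(data, value, group) {
  gv <- .get_groups(data, {{ value }}, {{ group }})
  if (nlevels(gv$group) < 2L || any(table(gv$group) < 2L)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  if (stats::var(gv$value) == 0) {
    warning("all observations identical; F undefined, returning p = 1")
    return(tibble::tibble(f = 0, p = 1,
                          df_between = nlevels(gv$group) - 1L,
                          df_within = length(gv$value) - nlevels(gv$group)))
  }
  fit <- stats::aov(value ~ group, data = data.frame(value = gv$value,
                                                     group = gv$group))
  s <- summary(fit)[[1]]
  tibble::tibble(f = s[["F value"]][1], p = s[["Pr(>F)"]][1],
                 df_between = s[["Df"]][1], df_within = s[["Df"]][2])
}

#' Tukey honest significant differences
#'
#' All pairwise comparisons with studentized-range adjusted p-values
#' ([stats::TukeyHSD()]), plus the pairwise fold change of group means and a
#' significance label: `"**"` for adjusted p <= 0.01, `"*"` for p <= 0.05,
#' `"n.s."` otherwise.
#'
#' @inheritParams one_way_anova
#' @return A tibble with one row per pair: `group1`, `group2` (fold change
#'   is `mean(group2)/mean(group1)`), `diff`, `fold_change`, `p_adj`,
#'   `significance`, and the overall ANOVA `f` and `p_anova`.
#' @export
tukey_hsd <- function(data, value, group) {
  gv <- .get_groups(data, {{ value }}, {{ group }})
  if (nlevels(gv$group) < 2L || any(table(gv$group) < 2L)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  means <- tapply(gv$value, gv$group, mean)
  if (stats::var(gv$value) == 0) {
    warning("all observations identical; comparisons are n.s.")
    pairs <- utils::combn(levels(gv$group), 2)
    return(tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                          diff = 0, fold_change = 1, p_adj = 1,
                          significance = "n.s.", f = 0, p_anova = 1))
  }
  fit <- stats::aov(value ~ group, data = data.frame(value = gv$value,
                                                     group = gv$group))
  tk <- stats::TukeyHSD(fit)$group
  an <- summary(fit)[[1]]
  labels <- strsplit(rownames(tk), "-", fixed = TRUE)
  # TukeyHSD labels pairs as "levelB-levelA" (difference B - A)
  g2 <- vapply(labels, `[`, character(1), 1)
  g1 <- vapply(labels, `[`, character(1), 2)
  p <- tk[, "p adj"]
  tibble::tibble(
    group1 = g1, group2 = g2,
    diff = unname(tk[, "diff"]),
    fold_change = as.numeric(means[g2] / means[g1]),
    p_adj = unname(p),
    significance = dplyr::case_when(p <= 0.01 ~ "**",
                                    p <= 0.05 ~ "*",
                                    TRUE ~ "n.s."),
    f = an[["F value"]][1],
    p_anova = an[["Pr(>F)"]][1]
  )
}

#' Condition comparison of quantified per-cell amounts
#'
#' Convenience wrapper producing, from a [quantify_samples()] table, the
#' per-condition summary (mean, SD, N of fmol/cell) together with fold
#' changes relative to a reference condition and Tukey-adjusted
#' significance labels.
#'
#' @param quant Quantification tibble with `condition` and `fmol_per_cell`.
#' @param reference Reference condition label (default: first condition in
#'   the table).
#' @return A list with elements `summary` (per condition) and `comparisons`
#'   (the [tukey_hsd()] table filtered to contrasts against the reference,
#'   with fold changes expressed as condition/reference).
#' @export
compare_conditions <- function(quant, reference = NULL) {
  if (is.null(reference)) reference <- quant$condition[1]
  if (!reference %in% quant$condition) {
    stop("reference condition not present: ", reference, call. = FALSE)
  }
  summary <- dplyr::summarise(
    dplyr::group_by(quant, .data$condition),
    mean_fmol_per_cell = mean(.data$fmol_per_cell),
    sd_fmol_per_cell = stats::sd(.data$fmol_per_cell),
    mean_mm = mean(.data$mm),
    n = dplyr::n(), .groups = "drop")
  tk <- tukey_hsd(quant, fmol_per_cell, condition)
  ref_rows <- tk$group1 == reference | tk$group2 == reference
  cmp <- tk[ref_rows, ]
  flip <- cmp$group2 == reference
  if (any(flip)) {
    tmp <- cmp$group1[flip]
    cmp$group1[flip] <- cmp$group2[flip]
    cmp$group2[flip] <- tmp
    cmp$fold_change[flip] <- 1 / cmp$fold_change[flip]
    cmp$diff[flip] <- -cmp$diff[flip]
  }
  list(summary = summary, comparisons = cmp)
}

#' Quantitative survey table
#'
#' Formats per-replicate quantification results into a species-by-analyte
#' survey: `"mean +/- sd"` (fmol/cell) for quantifiable analytes, `"+"` when
#' a signal is present but below the limit of quantification, `"-"` when no
#' signal is detected in any replicate.
#'
#' @param quant Tibble with columns `species`, `analyte`, `fmol_per_cell`,
#'   `censoring` (one row per replicate).
#' @param digits Significant digits for the formatted mean and SD
#'   (default 3).
#' @return A wide tibble, one row per species, one column per analyte.
#' @export
survey_table <- function(quant, digits = 3) {
  needed <- c("species", "analyte", "fmol_per_cell", "censoring")
  missing <- setdiff(needed, names(quant))
  if (length(missing) > 0L) {
    stop("quant table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fmt <- function(fmol, censoring) {
    if (all(censoring == "below_lod")) return("-")
    if (any(censoring != "quantifiable")) return("+")
    sprintf("%s ± %s", signif(mean(fmol), digits),
            signif(stats::sd(fmol), digits))
  }
  long <- dplyr::summarise(
    dplyr::group_by(quant, .data$species, .data$analyte),
    cell = fmt(.data$fmol_per_cell, .data$censoring), .groups = "drop")
  tidyr::pivot_wider(long, names_from = "analyte", values_from = "cell")
}
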