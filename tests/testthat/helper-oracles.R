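# Independent brute-force oracles. These deliberately avoid the package's
# own computational paths.

# NIST isotope masses/abundances, re-entered independently of R/elements.R
oracle_isotopes <- list(
  H = data.frame(mass = c(1.00782503207, 2.0141017778),
                 p = c(0.999885, 0.000115)),
  C = data.frame(mass = c(12, 13.0033548378), p = c(0.9893, 0.0107)),
  N = data.frame(mass = c(14.0030740048, 15.0001088982),
                 p = c(0.99636, 0.00364)),
  O = data.frame(mass = c(15.9949146196, 16.9991317, 17.9991610),
                 p = c(0.99757, 0.00038, 0.00205)),
  S = data.frame(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
                 p = c(0.9499, 0.0075, 0.0425, 0.0001))
)

# exhaustive isotopologue enumeration: all ways of distributing each
# element's atom count over its isotopes (multinomial probabilities),
# crossed over elements; returns shift/abundance centroids clustered at
# merge_tol, base peak = 1
oracle_isotope_pattern <- function(counts, merge_tol = 0.003) {
  compositions <- function(n, k) {
    if (k == 1) return(matrix(n, ncol = 1))
    out <- NULL
    for (i in 0:n) {
      rest <- compositions(n - i, k - 1)
      out <- rbind(out, cbind(i, rest))
    }
    out
  }
  per_element <- lapply(names(counts), function(el) {
    iso <- oracle_isotopes[[el]]
    n <- counts[[el]]
    comp <- compositions(n, nrow(iso))
    mono <- iso$mass[which.max(iso$p)]
    data.frame(
      shift = as.vector(comp %*% iso$mass) - n * mono,
      p = apply(comp, 1, function(x) stats::dmultinom(x, prob = iso$p))
    )
  })
  full <- Reduce(function(a, b) {
    data.frame(shift = as.vector(outer(a$shift, b$shift, `+`)),
               p = as.vector(outer(a$p, b$p)))
  }, per_element)
  full <- full[order(full$shift), ]
  grp <- cumsum(c(1, diff(full$shift) > merge_tol))
  shift <- tapply(full$shift * full$p, grp, sum) / tapply(full$p, grp, sum)
  p <- tapply(full$p, grp, sum)
  data.frame(shift = as.numeric(shift), abundance = as.numeric(p / max(p)))
}

# one-way ANOVA F from explicit sums of squares
oracle_anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v) {
    length(v) * (mean(v) - grand)^2
  }))
  ss_within <- sum(unlist(lapply(split(values, groups), function(v) {
    sum((v - mean(v))^2)
  })))
  df_b <- nlevels(groups) - 1
  df_w <- length(values) - nlevels(groups)
  (ss_between / df_b) / (ss_within / df_w)
}

# closed-form least squares (normal equations)
oracle_ls_origin <- function(x, y) sum(x * y) / sum(x^2)
oracle_pearson_r <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
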