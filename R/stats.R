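# Group-level statistics: two-group comparisons (t, K-S), one-way ANOVA,
# chi-square on category ratios, and the summary table (mean +/- SEM, n,
# test, p) used for cohort-level reporting. Significance is taken at
# p < 0.05 throughout.

sem <- function(x) stats::sd(x) / sqrt(length(x))

group_comparison <- function(test, statistic, p, sizes, means, sems) {
  structure(list(test = test, statistic = unname(statistic),
                 p = unname(p), sizes = sizes, means = means, sems = sems,
                 significant = is.finite(p) && p < 0.05),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<%s test: statistic %.4g, p %.4g%s>\n", x$test, x$statistic,
              x$p, if (x$significant) " *" else ""))
  invisible(x)
}

#' Compare two groups (t-test or Kolmogorov-Smirnov)
#'
#' @param a,b numeric samples.
#' @param test `"t"` (two-sided unpaired) or `"ks"` (two-sample K-S).
#' @param var_equal for the t-test: classic Student's t when TRUE, Welch
#'   when FALSE (default).
#' @return a `group_comparison` with statistic, p, group sizes and
#'   mean +/- SEM.
#' @export
compare_groups <- function(a, b, test = c("t", "ks"), var_equal = FALSE) {
  test <- match.arg(test)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (test == "t") {
    if (length(a) < 2 || length(b) < 2)
      stop("compare_groups: t-test needs n >= 2 per group")
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
      return(group_comparison("t", NA_real_, NA_real_,
                              c(length(a), length(b)),
                              c(mean(a), mean(b)), c(sem(a), sem(b))))
    r <- stats::t.test(a, b, var.equal = var_equal)
  } else {
    if (length(a) < 1 || length(b) < 1)
      stop("compare_groups: K-S needs n >= 1 per group")
    r <- suppressWarnings(stats::ks.test(a, b))
  }
  group_comparison(test, r$statistic, r$p.value, c(length(a), length(b)),
                   c(mean(a), mean(b)), c(sem(a), sem(b)))
}

#' One-way ANOVA across groups
#'
#' @param groups list of >= 2 numeric samples, each n >= 2.
#' @return a `group_comparison` with the F statistic and p value; when all
#'   within-group variances are zero the statistic is flagged undefined
#'   (NA).
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("anova_oneway: every group needs n >= 2")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  means <- vapply(groups, mean, numeric(1))
  sems <- vapply(groups, sem, numeric(1))
  sizes <- vapply(groups, length, numeric(1))
  if (all(vapply(groups, stats::sd, numeric(1)) == 0)) {
    stat <- if (stats::sd(means) == 0) 0 else NA_real_
    return(group_comparison("anova", stat, NA_real_, sizes, means, sems))
  }
  r <- stats::oneway.test(y ~ g, var.equal = TRUE)
  group_comparison("anova", r$statistic, r$p.value, sizes, means, sems)
}

#' Chi-square test on category ratios
#'
#' Pearson chi-square (no continuity correction) on a groups x categories
#' count table, expected counts from the margins; df = (rows-1) x (cols-1).
#'
#' @param table matrix of non-negative counts (e.g. 2 genotypes x 3 firing
#'   patterns).
#' @return a `group_comparison` with the chi-square statistic and p.
#' @export
chi_square_ratio <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("chi_square_ratio: negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi_square_ratio: zero margin")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  group_comparison("chi2", stat, p, rowSums(table),
                   rowSums(table) / sum(table), rep(NA_real_, nrow(table)))
}

#' Cohort summary table
#'
#' One row per metric: group means +/- SEM, group sizes, the test applied
#' and its p value. `n` is the number of cells. Tests: Welch t by default
#' (`var_equal = TRUE` for classic Student's t). An optional
#' Benjamini-Hochberg adjusted-p column can be added (`adjust = TRUE`); it
#' is an extra convenience, not part of the standard report.
#'
#' @param metrics data frame with columns `cell_id`, `group`, `metric`,
#'   `value`.
#' @param group_levels length-2 character vector ordering the groups
#'   (defaults to sorted unique values).
#' @param var_equal passed to [compare_groups].
#' @param adjust add a BH-adjusted p column.
#' @return data frame: `metric`, `group1`, `group2`, `n1`, `n2`, `mean1`,
#'   `sem1`, `mean2`, `sem2`, `test`, `statistic`, `p`, `significant`
#'   (and `p_adj` when requested).
#' @export
summary_table <- function(metrics, group_levels = NULL, var_equal = FALSE,
                          adjust = FALSE) {
  need <- c("cell_id", "group", "metric", "value")
  if (!all(need %in% names(metrics)))
    stop("summary_table: metrics must have columns ",
         paste(need, collapse = ", "))
  if (nrow(metrics) == 0) {
    out <- data.frame(metric = character(0), group1 = character(0),
                      group2 = character(0), n1 = integer(0),
                      n2 = integer(0), mean1 = numeric(0),
                      sem1 = numeric(0), mean2 = numeric(0),
                      sem2 = numeric(0), test = character(0),
                      statistic = numeric(0), p = numeric(0),
                      significant = logical(0))
    return(out)
  }
  if (is.null(group_levels)) group_levels <- sort(unique(metrics$group))
  if (!all(metrics$group %in% group_levels))
    stop("summary_table: group labels not in group_levels")
  if (length(group_levels) != 2)
    stop("summary_table: exactly two groups expected")
  rows <- lapply(unique(metrics$metric), function(m) {
    sub <- metrics[metrics$metric == m, ]
    a <- sub$value[sub$group == group_levels[1]]
    b <- sub$value[sub$group == group_levels[2]]
    cmp <- compare_groups(a, b, "t", var_equal = var_equal)
    data.frame(metric = m, group1 = group_levels[1],
               group2 = group_levels[2],
               n1 = cmp$sizes[1], n2 = cmp$sizes[2],
               mean1 = cmp$means[1], sem1 = cmp$sems[1],
               mean2 = cmp$means[2], sem2 = cmp$sems[2],
               test = cmp$test, statistic = cmp$statistic, p = cmp$p,
               significant = isTRUE(cmp$significant))
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
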