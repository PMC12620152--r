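.stat_report <- function(test, statistic, p, method = NA_character_,
                         p_adjusted = NA_real_, alpha = 0.05) {
  structure(list(test = test, statistic = unname(statistic), p = p,
                 p_adjusted = p_adjusted, adjustment = method,
                 significant = !is.na(p_adjusted) && p_adjusted <= alpha),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g", x$test, x$statistic, x$p))
  if (!is.na(x$p_adjusted))
    cat(sprintf(", p_adj (%s) = %.4g%s", x$adjustment, x$p_adjusted,
                if (x$significant) " *" else ""))
  cat("\n")
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' @param x Numeric sample (n >= 3).
#' @param alpha Flagging level.
#' @return List with `p`, `non_normal` (flag at `alpha`) and `degenerate`
#'   (TRUE for an all-equal sample, which is flagged non-normal with
#'   `p = NA`).
#' @export
normality_check <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) .stopf("need at least 3 observations")
  if (diff(range(x)) == 0)
    return(list(p = NA_real_, non_normal = TRUE, degenerate = TRUE))
  p <- stats::shapiro.test(x)$p.value
  list(p = p, non_normal = p < alpha, degenerate = FALSE)
}

#' Paired two-tailed Wilcoxon signed-rank test
#'
#' Zero differences are discarded (classic signed-rank convention) before
#' ranking. The exact distribution is used for up to 25 non-zero, untied
#' differences; the normal approximation (with continuity correction)
#' otherwise, or always when `exact = FALSE`.
#'
#' @param x,y Paired samples of equal length.
#' @param exact `NULL` (auto), `TRUE` or `FALSE`.
#' @return A `stat_report` with the signed-rank statistic V and two-tailed
#'   p-value. All-zero differences give `p = 1` with a warning.
#' @export
wilcoxon_paired <- function(x, y, exact = NULL) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  d <- x - y
  d <- d[!is.na(d)]
  if (all(d == 0)) {
    warning("all paired differences are zero", call. = FALSE)
    return(.stat_report("Wilcoxon signed-rank", NA_real_, 1))
  }
  nz <- d[d != 0]
  if (is.null(exact)) exact <- length(nz) <= 25
  suppressWarnings(
    wt <- stats::wilcox.test(nz, alternative = "two.sided",
                             exact = exact, correct = TRUE))
  .stat_report("Wilcoxon signed-rank", wt$statistic, wt$p.value)
}

#' Friedman test across paired conditions
#'
#' @param values Matrix with one row per subject and one column per
#'   condition (>= 2 subjects, >= 3 conditions). Ties receive average
#'   ranks.
#' @return A `stat_report` with the Friedman chi-square statistic.
#' @export
friedman_conditions <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 3L) .stopf("need at least 3 conditions")
  if (nrow(values) < 2L) .stopf("need at least 2 subjects")
  if (all(apply(values, 1, function(r) diff(range(r)) == 0)))
    return(.stat_report("Friedman", 0, 1))  # every subject fully tied
  ft <- stats::friedman.test(values)
  .stat_report("Friedman", ft$statistic, ft$p.value)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)` over a family of `m` p-values, with decisions at
#' `alpha`.
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @param alpha Significance level for the decision column.
#' @return Data frame with `p`, `p_adj`, `significant`.
#' @export
bonferroni_adjust <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) .stopf("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "bonferroni")
  data.frame(p = p, p_adj = adj, significant = adj <= alpha)
}

#' Distribution-free confidence interval for the median
#'
#' Order-statistic (binomial) CI: the widest symmetric pair of order
#' statistics `(x_(l), x_(n+1-l))` whose exact coverage
#' `1 - 2 pbinom(l-1, n, 1/2)` reaches the requested level. For samples too
#' small to attain the level even with `(x_(1), x_(n))`, the full range is
#' returned and flagged.
#'
#' @param x Numeric sample (n >= 1).
#' @param level Target coverage.
#' @return List with `median`, `lower`, `upper`, `coverage` (exact
#'   achieved coverage) and `attained` (FALSE when the sample is too small
#'   for the level).
#' @export
median_ci <- function(x, level = 0.95) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 1L) .stopf("empty sample")
  med <- stats::median(x)
  if (n == 1L)
    return(list(median = med, lower = x[1], upper = x[1], coverage = 0,
                attained = FALSE))
  # largest l with P(X_(l) <= median <= X_(n+1-l)) >= level
  l <- 0L
  while (l + 1L <= n / 2 &&
         1 - 2 * stats::pbinom(l, n, 0.5) >= level) l <- l + 1L
  if (l == 0L)
    return(list(median = med, lower = x[1], upper = x[n],
                coverage = 1 - 2 * stats::pbinom(0, n, 0.5),
                attained = FALSE))
  list(median = med, lower = x[l], upper = x[n + 1L - l],
       coverage = 1 - 2 * stats::pbinom(l - 1L, n, 0.5), attained = TRUE)
}
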