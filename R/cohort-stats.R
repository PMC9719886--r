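# Univariable group comparisons: nonparametric two-sample tests for the
# continuous DECT and morphology variables, exact/asymptotic contingency
# tests for the categorical ones, and rank correlation for the lesion-node
# relationship.  All p-values are two-sided.

#' Mann-Whitney U test
#'
#' U is computed with midranks for ties.  The p-value is exact (full
#' enumeration of the permutation distribution) when both groups have at
#' most 10 observations and there are no ties, and otherwise uses the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples for the two groups, each nonempty.
#' @return List with \code{statistic} (U for \code{x} relative to \code{y}),
#'   \code{p_value} and \code{method}.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  use_exact <- length(x) <= 10L && length(y) <= 10L &&
    !anyDuplicated(c(x, y))
  wt <- stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (use_exact) "exact" else "normal approximation")
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) no more likely
#' than the observed one.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return List with \code{p_value} and \code{odds_ratio} (conditional MLE).
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L))) {
    stop("fisher_exact_2x2 requires a 2x2 table; use chi_squared for larger tables",
         call. = FALSE)
  }
  check_counts(table)
  ft <- stats::fisher.test(table)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Pearson chi-squared test of independence
#'
#' Uncorrected Pearson statistic with df = (r-1)(c-1); expected counts must
#' be positive (no zero row or column margins).
#'
#' @param table r x c matrix of nonnegative integer counts, r, c >= 2.
#' @return List with \code{statistic}, \code{df} and \code{p_value}.
#' @export
chi_squared <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("chi_squared requires at least a 2x2 table", call. = FALSE)
  }
  check_counts(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi_squared is undefined with a zero row or column margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

check_counts <- function(table) {
  if (any(!is.finite(table)) || any(table < 0) ||
      any(abs(table - round(table)) > 1e-8)) {
    stop("contingency table must contain nonnegative integer counts", call. = FALSE)
  }
  invisible(table)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; two-sided p-value from the t
#' approximation with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 (pairs with a missing
#'   value are dropped).
#' @return List with \code{rho}, \code{p_value} and \code{n}.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("correlation is undefined for a constant vector", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Compare one variable between the metastasis and non-metastasis groups
#'
#' Continuous variables: Mann-Whitney U test with per-group mean, SD and
#' range.  Categorical variables: Fisher exact test for 2x2 tables, Pearson
#' chi-squared for larger ones, with per-group counts.  Rows with a missing
#' value of the variable are excluded from that comparison and the exclusion
#' count reported.
#'
#' @param cohort Cohort data frame with a binary \code{group} column
#'   (1 = metastasis).
#' @param variable Column name to compare.
#' @param type \code{"continuous"} or \code{"categorical"}.
#' @return An object of class \code{group_comparison}.
#' @export
compare_groups <- function(cohort, variable,
                           type = c("continuous", "categorical")) {
  type <- match.arg(type)
  if (!variable %in% names(cohort)) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  if (!all(cohort$group %in% c(0L, 1L))) {
    stop("group column must be binary 0/1", call. = FALSE)
  }
  v <- cohort[[variable]]
  g <- cohort$group
  ok <- !is.na(v)
  n_excluded <- sum(!ok)
  v <- v[ok]
  g <- g[ok]
  if (length(unique(g)) < 2L) {
    stop("both groups must be present after removing missing values of '",
         variable, "'", call. = FALSE)
  }
  if (type == "continuous") {
    a <- v[g == 1L]
    b <- v[g == 0L]
    test <- mann_whitney(a, b)
    summ <- data.frame(
      group = c("metastasis", "non_metastasis"),
      n = c(length(a), length(b)),
      mean = c(mean(a), mean(b)),
      sd = c(stats::sd(a), stats::sd(b)),
      min = c(min(a), min(b)),
      max = c(max(a), max(b))
    )
    res <- list(variable = variable, type = type, summary = summ,
                test = "Mann-Whitney U", statistic = test$statistic,
                p_value = test$p_value, n_excluded = n_excluded)
  } else {
    tab <- table(factor(g, levels = c(1L, 0L),
                        labels = c("metastasis", "non_metastasis")),
                 v)
    if (ncol(tab) < 2L) {
      stop("variable '", variable, "' has a single observed category", call. = FALSE)
    }
    if (nrow(tab) == 2L && ncol(tab) == 2L) {
      test <- fisher_exact_2x2(tab)
      res <- list(variable = variable, type = type, summary = tab,
                  test = "Fisher exact", statistic = NA_real_,
                  p_value = test$p_value, n_excluded = n_excluded)
    } else {
      test <- chi_squared(tab)
      res <- list(variable = variable, type = type, summary = tab,
                  test = "chi-squared", statistic = test$statistic,
                  p_value = test$p_value, n_excluded = n_excluded)
    }
  }
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of '%s' (%s): %s test, p = %.4g\n",
              x$variable, x$type, x$test, x$p_value))
  if (x$n_excluded > 0) {
    cat(sprintf("  (%d rows excluded for missing values)\n", x$n_excluded))
  }
  print(x$summary, ...)
  invisible(x)
}
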