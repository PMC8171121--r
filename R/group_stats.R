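# Demographic/group-comparison machinery for small two-group cohorts:
# mean (SD) summaries, pooled t-tests for continuous traits, uncorrected
# Pearson chi-square for binary traits, and Shapiro-Wilk normality checks.
#
# Conventions verified against the reference cohort's printed table: the
# parenthetical dispersions are population (divide-by-n) SDs, binary traits
# use the chi-square without continuity correction, and continuous traits
# the equal-variance pooled t.

#' Mean and standard deviation
#'
#' @param values Numeric vector, length >= 1.
#' @param population If `TRUE` (default) the population SD (divide by n);
#'   otherwise the sample SD (divide by n-1).
#' @return List with `mean` and `sd`.
#' @export
mean_sd <- function(values, population = TRUE) {
  if (!length(values)) stop("empty input")
  m <- mean(values)
  n <- length(values)
  s <- if (n == 1L) 0 else {
    ss <- sum((values - m)^2)
    sqrt(ss / if (population) n else n - 1)
  }
  list(mean = m, sd = s)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Closed-form `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 df;
#' an optional Yates continuity correction subtracts N/2 from |ad - bc|.
#' A zero margin gives chi2 = 0, p = 1 by convention.
#'
#' @param a,b,c,d Non-negative integer cell counts (row-wise:
#'   `a b / c d`).
#' @param yates Apply the continuity correction (default `FALSE`).
#' @return List with `chi2` and `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d, yates = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if (any(cells != round(cells))) stop("cell counts must be integers")
  N <- sum(cells)
  if (N == 0) stop("table total must be positive")
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) return(list(chi2 = 0, p = 1))
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - N / 2)
  chi2 <- N * num^2 / prod(margins)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard Royston approximation with the
#' pipeline's degenerate-input convention (a constant vector is an error
#' rather than `NaN`).
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  if (length(values) < 3L || length(values) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("degenerate input: all values identical")
  st <- stats::shapiro.test(values)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Two-group demographic comparison table
#'
#' Continuous traits are summarized as mean (population SD) per group and
#' compared by the pooled-variance t-test; binary traits as n (%) per group
#' and compared by the uncorrected chi-square.
#'
#' @param subjects Per-subject data frame.
#' @param group_col Name of the grouping column.
#' @param case_level Value of `group_col` identifying the case group.
#' @param continuous Character vector of continuous column names.
#' @param binary Named character vector: names are column names, values the
#'   level counted as positive (e.g. `c(gender = "man", chd = "yes")`).
#' @return Data frame with one row per trait: `characteristic`, `type`,
#'   formatted `case` / `control` summaries, numeric `p`, and formatted
#'   `p_fmt` (3 decimals). Attribute `"n"` holds the group sizes.
#' @export
demographic_table <- function(subjects, group_col = "group",
                              case_level = "case",
                              continuous = character(0),
                              binary = character(0)) {
  g <- subjects[[group_col]]
  if (is.null(g)) stop("missing group column '", group_col, "'")
  if (anyNA(g)) stop("subject with missing group assignment")
  is_case <- g == case_level
  if (length(unique(g)) != 2L) stop("exactly two groups required")
  n_case <- sum(is_case); n_ctrl <- sum(!is_case)
  rows <- list()
  for (col in continuous) {
    xs <- subjects[[col]][is_case]; ys <- subjects[[col]][!is_case]
    sc <- mean_sd(xs); sn <- mean_sd(ys)
    p <- if (stats::sd(xs) == 0 && stats::sd(ys) == 0 && mean(xs) == mean(ys)) 1
         else t_test_two_sample(xs, ys, equal_variance = TRUE)$p
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = col, type = "continuous",
      case = sprintf("%.2f (%.2f)", sc$mean, sc$sd),
      control = sprintf("%.2f (%.2f)", sn$mean, sn$sd),
      p = p, stringsAsFactors = FALSE)
  }
  for (i in seq_along(binary)) {
    col <- names(binary)[i]; pos <- binary[[i]]
    a <- sum(subjects[[col]][is_case] == pos)
    c_ <- sum(subjects[[col]][!is_case] == pos)
    res <- chi_square_2x2(a, n_case - a, c_, n_ctrl - c_, yates = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = col, type = "binary",
      case = sprintf("%d (%.0f)", a, 100 * a / n_case),
      control = sprintf("%d (%.0f)", c_, 100 * c_ / n_ctrl),
      p = res$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_fmt <- sprintf("%.3f", out$p)
  rownames(out) <- NULL
  attr(out, "n") <- c(case = n_case, control = n_ctrl)
  out
}

#' The packaged eight-subject reference cohort
#'
#' Per-subject demographics of the GSE163943 cohort (4 delirium cases,
#' 4 controls after orthopedic surgery), shipped as a plain-text fixture.
#'
#' @return Data frame with one row per subject; `delirium == "yes"` marks
#'   the case group.
#' @export
pod_cohort <- function() {
  path <- system.file("extdata", "pod_cohort.tsv", package = "podlnc",
                      mustWork = TRUE)
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
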