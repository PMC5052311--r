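#' Baseline cohort comparison tests
#'
#' The three tests used for case-control baseline tables: Pearson's
#' chi-square (no continuity correction) for r x c categorical tables,
#' Fisher's exact test for 2 x 2 tables, and the two-sided pooled-variance
#' independent t test for continuous covariates. All delegate to the
#' corresponding `stats` routines; the wrappers pin down the exact variants
#' and the degenerate-case conventions.
#'
#' @param table Matrix of non-negative counts (rows = classes).
#' @return `chi_square_test`: list with `statistic` (Pearson
#'   \eqn{\sum (O-E)^2/E}), `df` = (r-1)(c-1) and the upper-tail `p`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (sum(table) <= 0 || any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-square test needs non-zero row and column margins", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' @rdname chi_square_test
#' @return `fisher_exact`: the two-sided p-value (sum of hypergeometric
#'   probabilities no larger than the observed table's).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    stop("fisher_exact requires a 2x2 table", call. = FALSE)
  }
  stats::fisher.test(table)$p.value
}

#' @rdname chi_square_test
#' @param x,y Numeric samples, each of size >= 2.
#' @return `t_test_independent`: list with `t`, `df`, two-sided `p`.
#'   Identical constant samples give `t = 0, p = 1` by convention; constant
#'   samples with different means (zero pooled variance) are an error.
#' @export
t_test_independent <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    stop("zero pooled variance with unequal means: t statistic undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
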