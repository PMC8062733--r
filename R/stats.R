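#' Wilcoxon rank-sum test with explicit exact/approximate switching
#'
#' Compares two samples with the Wilcoxon-Mann-Whitney rank-sum test, the
#' test used throughout the pipeline for dose comparisons and quartile
#' contrasts. The p-value is exact (full enumeration of rank assignments)
#' when both samples have at most ten observations and there are no ties;
#' otherwise a tie-corrected normal approximation with continuity correction
#' is used. When the combined sample is constant (zero rank variance) no
#' evidence exists in either direction and the p-value is 0.5 for one-sided
#' alternatives and 1 for the two-sided alternative.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param alternative One of `"two.sided"`, `"greater"` (x tends larger than
#'   y) or `"less"`.
#' @return An object of class `"ifn_test"`: a list with `statistic` (the
#'   Mann-Whitney U for `x`), `p_value`, `alternative`, `method`, `exact`
#'   (logical) and sample sizes `n1`, `n2`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(10, 11, 12), alternative = "less")
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("rank_sum_test: both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("rank_sum_test: NA values not allowed")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && n1 <= 10L && n2 <= 10L
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (stats::var(r) == 0) {
    # all observations tied: no ordering evidence at all
    p <- if (alternative == "two.sided") 1 else 0.5
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      x, y, alternative = alternative, exact = exact, correct = TRUE
    ))
    p <- min(1, wt$p.value)
  }
  structure(list(
    statistic = unname(u), p_value = p, alternative = alternative,
    method = if (exact) "Wilcoxon rank-sum (exact)" else
      "Wilcoxon rank-sum (normal approximation, tie and continuity corrected)",
    exact = exact, n1 = n1, n2 = n2
  ), class = "ifn_test")
}

#' Fisher's exact test on a 2x2 table
#'
#' Hypergeometric exact test used for the promoter-peak enrichment contrast
#' between enhancement quartiles. The two-sided p-value is the sum of
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one. A table with an empty margin carries no
#' information; its p-value is reported as 1 with `degenerate = TRUE`.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @param alternative One of `"two.sided"`, `"greater"`, `"less"` (refers to
#'   the odds ratio of the first cell).
#' @return An `"ifn_test"` object with `statistic` (the odds ratio estimate),
#'   `p_value` and a `degenerate` flag.
#' @examples
#' fisher_exact(matrix(c(25, 10, 20, 35), nrow = 2))
#' @export
fisher_exact <- function(table, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("fisher_exact: table must be 2x2")
  if (anyNA(table) || any(table < 0) || any(table != round(table)))
    stop("fisher_exact: cells must be non-negative integers")
  degenerate <- any(rowSums(table) == 0) || any(colSums(table) == 0)
  if (degenerate) {
    res <- list(statistic = NA_real_, p_value = 1)
  } else {
    ft <- stats::fisher.test(table, alternative = alternative)
    res <- list(statistic = unname(ft$estimate), p_value = ft$p.value)
  }
  structure(list(
    statistic = res$statistic, p_value = res$p_value,
    alternative = alternative, method = "Fisher exact (hypergeometric)",
    degenerate = degenerate, n1 = sum(table[1, ]), n2 = sum(table[2, ])
  ), class = "ifn_test")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment: the i-th smallest p-value is
#' replaced by `min_{j >= i} (m / j) p_(j)`, capped at 1, and values are
#' returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("bh_fdr: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' @export
print.ifn_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  n1 = %d, n2 = %d, alternative = %s\n", x$n1, x$n2, x$alternative))
  cat(sprintf("  statistic = %s, p = %.4g\n",
              format(x$statistic, digits = 4), x$p_value))
  if (isTRUE(x$degenerate)) cat("  (degenerate table: empty margin)\n")
  invisible(x)
}
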