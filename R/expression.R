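# TMM scaling factor of column `obs` against column `ref` (counts vectors,
# library sizes nO, nR). Weighted trimmed mean of M-values: trim 30% of the
# log-ratios and 5% of the absolute intensities, weight by inverse
# asymptotic (binomial) variance.
.tmm_factor <- function(obs, ref, nO, nR, logratio_trim = 0.30,
                        sum_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0L) return(1)
  m <- log2((obs / nO) / (ref / nR))
  a <- (log2(obs / nO) + log2(ref / nR)) / 2
  w <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  finite <- is.finite(m) & is.finite(a)
  m <- m[finite]; a <- a[finite]; w <- w[finite]
  n <- length(m)
  if (n == 0L) return(1)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m, ties.method = "first") >= lo_m &
    rank(m, ties.method = "first") <= hi_m &
    rank(a, ties.method = "first") >= lo_a &
    rank(a, ties.method = "first") <= hi_a
  if (!any(keep)) return(1)
  f <- sum(m[keep] / w[keep]) / sum(1 / w[keep])
  2^f
}

#' Normalize a count matrix to CPM and RPKM
#'
#' Counts-per-million use the effective library size: the raw column sum
#' (`method = "libsize"`) or the raw sum times a trimmed-mean-of-M-values
#' factor (`method = "tmm"`; log-ratio trim 0.30, absolute-intensity trim
#' 0.05, reference column the one whose upper-quartile CPM is closest to
#' the mean, factors renormalized to geometric mean 1). RPKM divides CPM by
#' gene length in kb.
#'
#' @param counts Non-negative integer matrix, genes x samples, with
#'   rownames.
#' @param lengths Named numeric vector of gene lengths (bp), covering all
#'   rows of `counts`.
#' @param method `"tmm"` (default) or `"libsize"`.
#' @return A list of class `"expr_norm"`: `cpm`, `rpkm`, `factors`,
#'   `lib_size`, `lengths`, `counts`, `conditions` (parsed column
#'   metadata).
#' @export
normalize_counts <- function(counts, lengths, method = c("tmm", "libsize")) {
  method <- match.arg(method)
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(names(lengths))) {
    stopifnot(length(lengths) == nrow(counts))
    names(lengths) <- rownames(counts)
  }
  if (!all(rownames(counts) %in% names(lengths)))
    stop("gene lengths missing for some genes")
  lengths <- lengths[rownames(counts)]
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size in column(s): ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  if (method == "tmm" && ncol(counts) > 1L) {
    cpm0 <- t(t(counts) / lib) * 1e6
    uq <- apply(cpm0, 2, stats::quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
    f <- vapply(seq_len(ncol(counts)), function(j)
      .tmm_factor(counts[, j], counts[, ref], lib[j], lib[ref]), 0)
    f <- f / exp(mean(log(f)))  # geometric mean 1
  } else {
    f <- rep(1, ncol(counts))
  }
  eff <- lib * f
  cpm <- t(t(counts) / eff) * 1e6
  rpkm <- cpm / (lengths / 1e3)
  structure(list(cpm = cpm, rpkm = rpkm, factors = f, lib_size = lib,
                 lengths = lengths, counts = counts,
                 conditions = parse_conditions(colnames(counts))),
            class = "expr_norm")
}

#' @export
print.expr_norm <- function(x, ...) {
  cat(sprintf("Normalized expression: %d genes x %d samples\n",
              nrow(x$cpm), ncol(x$cpm)))
  cat("  TMM factors: ", paste(sprintf("%.3f", x$factors), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Expressed-gene filter
#'
#' Genes below `threshold` CPM in every sample are excluded; a gene is
#' retained as soon as one sample reaches the threshold (boundary
#' inclusive).
#'
#' @param norm An `"expr_norm"` object.
#' @param threshold CPM threshold (default 2).
#' @return Character vector of retained gene identifiers.
#' @export
filter_expressed <- function(norm, threshold = 2) {
  stopifnot(inherits(norm, "expr_norm"))
  keep <- apply(norm$cpm, 1, function(v) any(v >= threshold))
  rownames(norm$cpm)[keep]
}

#' Pseudocounted expression fold-change
#'
#' @param rpkm_stim,rpkm_basal Non-negative RPKM values (vectors recycle).
#' @param pseudocount Pseudocount added to both terms (default 1 RPKM).
#' @return `(rpkm_stim + pseudocount) / (rpkm_basal + pseudocount)`.
#' @examples
#' fold_change(3, 1)  # 2
#' @export
fold_change <- function(rpkm_stim, rpkm_basal, pseudocount = 1) {
  stopifnot(all(rpkm_stim >= 0), all(rpkm_basal >= 0))
  (rpkm_stim + pseudocount) / (rpkm_basal + pseudocount)
}

# mean RPKM per gene over the selected columns
.rpkm_mean <- function(norm, cols) {
  rowMeans(norm$rpkm[, cols, drop = FALSE])
}

#' Select matrix columns by condition
#'
#' @param norm An `"expr_norm"` object (or a condition data frame from
#'   [parse_conditions()]).
#' @param stimulus,dose,time Selectors; NULL means any.
#' @return Character vector of matching column names.
#' @export
select_condition <- function(norm, stimulus = NULL, dose = NULL, time = NULL) {
  meta <- if (inherits(norm, "expr_norm")) norm$conditions else norm
  keep <- meta$parsed
  if (!is.null(stimulus)) keep <- keep & meta$stimulus == stimulus
  if (!is.null(dose)) keep <- keep & meta$dose == dose
  if (!is.null(time)) keep <- keep & meta$time == time
  meta$column[keep]
}

# Welch t-test on log2(RPKM + pseudocount) replicate values, with the
# zero-variance degenerate cases resolved by the effect: identical groups
# with zero spread give p = 1, separated groups with zero spread give p = 0.
.welch_log_rpkm <- function(stim_vals, basal_vals, pseudocount) {
  a <- log2(stim_vals + pseudocount)
  b <- log2(basal_vals + pseudocount)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Call interferon-stimulated genes
#'
#' For every gene, the fold-change of each stimulated timepoint over basal
#' is computed from replicate-mean RPKM with the pseudocount rule, and the
#' maximum over timepoints is the gene's fold-change. The p-value is a
#' two-sided Welch t-test on log2(RPKM + pseudocount) replicates at the
#' maximal-fold timepoint, BH-adjusted across all tested genes. Membership
#' requires adjusted FDR below `fdr` and fold above `fold`.
#'
#' @param norm An `"expr_norm"` object.
#' @param stim_cols Character vector of stimulated column names (may span
#'   several timepoints).
#' @param basal_cols Character vector of basal column names (>= 2
#'   replicates unless `fold_only`).
#' @param fdr,fold ISG thresholds (defaults 0.05 and 2).
#' @param pseudocount RPKM pseudocount.
#' @param genes Genes to test (default: all rows); typically the expressed
#'   set.
#' @param fold_only Skip the statistical test (single-replicate designs)
#'   and call membership on fold alone.
#' @return A data frame of class `"isg_table"`: `gene_id`, `max_fold`,
#'   `p_value`, `fdr`, `isg`.
#' @export
call_isgs <- function(norm, stim_cols, basal_cols, fdr = 0.05, fold = 2,
                      pseudocount = 1, genes = NULL, fold_only = FALSE) {
  stopifnot(inherits(norm, "expr_norm"))
  if (is.null(genes)) genes <- rownames(norm$rpkm)
  missing <- setdiff(genes, rownames(norm$rpkm))
  if (length(missing)) stop("genes not in matrix: ", paste(utils::head(missing), collapse = ", "))
  if (!fold_only && (length(stim_cols) < 2L || length(basal_cols) < 2L))
    stop("need >= 2 replicates per condition for the test; ",
         "set fold_only = TRUE for a fold-threshold-only call")
  meta <- norm$conditions
  stim_meta <- meta[match(stim_cols, meta$column), , drop = FALSE]
  by_time <- split(stim_cols, stim_meta$time)
  rpkm <- norm$rpkm[genes, , drop = FALSE]
  basal_mean <- rowMeans(rpkm[, basal_cols, drop = FALSE])
  fold_by_time <- vapply(by_time, function(cc)
    fold_change(rowMeans(rpkm[, cc, drop = FALSE]), basal_mean, pseudocount),
    numeric(length(genes)))
  fold_by_time <- matrix(fold_by_time, nrow = length(genes),
                         dimnames = list(genes, names(by_time)))
  max_fold <- apply(fold_by_time, 1, max)
  which_t <- names(by_time)[apply(fold_by_time, 1, which.max)]
  if (fold_only) {
    p <- rep(NA_real_, length(genes)); q <- rep(NA_real_, length(genes))
    isg <- max_fold > fold
  } else {
    p <- vapply(seq_along(genes), function(i) {
      cc <- by_time[[which_t[i]]]
      .welch_log_rpkm(rpkm[i, cc], rpkm[i, basal_cols], pseudocount)
    }, 0)
    q <- bh_fdr(p)
    isg <- q < fdr & max_fold > fold
  }
  out <- data.frame(gene_id = genes, max_fold = max_fold, p_value = p,
                    fdr = q, isg = isg, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("isg_table", "data.frame")
  out
}

#' Induced fraction of a gene set
#'
#' Count and fraction of genes whose maximal pseudocounted fold-change over
#' basal exceeds `fold`.
#'
#' @param gene_set Character vector of gene identifiers (non-empty).
#' @param norm An `"expr_norm"` object.
#' @param stim_cols,basal_cols Column selections as in [call_isgs()].
#' @param fold Fold threshold (default 2).
#' @param pseudocount RPKM pseudocount.
#' @return A list with `count`, `total`, `fraction` and `percent`
#'   (nearest-integer percent).
#' @examples
#' \dontrun{induced_fraction(genes, norm, stim, basal)}
#' @export
induced_fraction <- function(gene_set, norm, stim_cols, basal_cols, fold = 2,
                             pseudocount = 1) {
  if (length(gene_set) == 0L) stop("induced_fraction: empty gene set")
  tab <- call_isgs(norm, stim_cols, basal_cols, fold = fold,
                   pseudocount = pseudocount, genes = gene_set,
                   fold_only = TRUE)
  count <- sum(tab$max_fold > fold)
  list(count = count, total = length(gene_set),
       fraction = count / length(gene_set),
       percent = round(100 * count / length(gene_set)))
}
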