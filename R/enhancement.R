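#' Enhancement score
#'
#' Quantifies synergy between the two single stimuli: the ratio of
#' mixed-stimulation expression to the sum of the single-stimulation
#' expressions, with the 1-RPKM pseudocount applied to each term
#' independently:
#' `ES = (mixed + 1) / ((beta + 1) + (gamma + 1))`.
#' Under this convention an additive response (mixed response equal to the
#' sum of the single responses) scores close to 1, and supra-additive
#' (synergistic) induction scores above 1.
#'
#' @param rpkm_mixed,rpkm_beta,rpkm_gamma Non-negative RPKM values.
#' @param pseudocount Pseudocount added to every term (default 1 RPKM).
#' @return Numeric vector of enhancement scores.
#' @examples
#' enhancement_score(7, 1, 1)  # 2: two-fold synergy
#' enhancement_score(3, 1, 1)  # 1: additive null
#' @export
enhancement_score <- function(rpkm_mixed, rpkm_beta, rpkm_gamma,
                              pseudocount = 1) {
  stopifnot(all(rpkm_mixed >= 0), all(rpkm_beta >= 0), all(rpkm_gamma >= 0))
  (rpkm_mixed + pseudocount) /
    ((rpkm_beta + pseudocount) + (rpkm_gamma + pseudocount))
}

#' Partition genes into top/bottom score quartiles
#'
#' The top and bottom quartiles each contain `ceiling(n / 4)` genes by
#' score rank (ties broken by gene identifier); everything else is MID.
#' The reported thresholds are the boundary score values (smallest TOP
#' score and largest BOTTOM score).
#'
#' @param scores Numeric vector of finite scores.
#' @param gene_ids Gene identifiers, same length as `scores`.
#' @return A list of class `"quartile_partition"`: `assignment` (data frame
#'   `gene_id`, `score`, `quartile`), `q` (quartile size), `top_threshold`,
#'   `bottom_threshold`.
#' @export
quartile_partition <- function(scores, gene_ids) {
  if (length(scores) < 4L) stop("quartile_partition: need at least 4 records")
  if (length(scores) != length(gene_ids)) stop("scores and gene_ids differ in length")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n <- length(scores)
  q <- ceiling(n / 4)
  ord <- order(-scores, gene_ids)  # descending score, id tie-break
  quart <- rep("MID", n)
  quart[ord[seq_len(q)]] <- "TOP"
  quart[rev(ord)[seq_len(q)]] <- "BOTTOM"
  out <- list(
    assignment = data.frame(gene_id = gene_ids, score = scores,
                            quartile = quart, stringsAsFactors = FALSE),
    q = q,
    top_threshold = min(scores[quart == "TOP"]),
    bottom_threshold = max(scores[quart == "BOTTOM"])
  )
  class(out) <- "quartile_partition"
  out
}

#' @export
print.quartile_partition <- function(x, ...) {
  cat(sprintf("Quartile partition: n = %d, q = %d per tail\n",
              nrow(x$assignment), x$q))
  cat(sprintf("  TOP: ES >= %.3f; BOTTOM: ES <= %.3f\n",
              x$top_threshold, x$bottom_threshold))
  invisible(x)
}

#' GC fraction of a sequence
#'
#' `(G + C) / (A + C + G + T)`; N bases are excluded from numerator and
#' denominator. An all-N window is undefined and returns NA.
#'
#' @param seq Character string over A/C/G/T/N.
#' @return GC fraction in \[0, 1\], or NA.
#' @examples
#' gc_content("ACGT")  # 0.5
#' @export
gc_content <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  gc <- sum(chars %in% c("G", "C"))
  acgt <- sum(chars %in% c("A", "C", "G", "T"))
  if (acgt == 0L) return(NA_real_)
  gc / acgt
}

#' Promoter GC content around gene TSSs
#'
#' GC fraction of the strand-agnostic window `gc_window` centered on each
#' TSS (GC content is invariant under reverse complement). Windows are
#' clipped at chromosome bounds and flagged.
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @param tss TSS annotation data frame.
#' @param gc_window Signed window, default `c(-300, 300)`.
#' @return A data frame `gene_id`, `gc`, `clipped`.
#' @export
promoter_gc <- function(genome, tss, gc_window = c(-300, 300)) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  gc <- numeric(nrow(tss)); clipped <- logical(nrow(tss))
  for (i in seq_len(nrow(tss))) {
    L <- lens[[tss$chrom[i]]]
    from <- tss$tss[i] + gc_window[1]
    to <- tss$tss[i] + gc_window[2]
    clipped[i] <- from < 0 || to > L
    from <- max(0, from); to <- min(L, to)
    gc[i] <- gc_content(get_sequence(genome, tss$chrom[i], from, to))
  }
  data.frame(gene_id = tss$gene_id, gc = gc, clipped = clipped,
             stringsAsFactors = FALSE)
}

#' Assemble per-gene enhancement records
#'
#' One record per gene of the ISG set: the Enhancement score with its
#' condition RPKMs, the TOP/BOTTOM/MID quartile, the promoter GC content,
#' and the promoter-peak annotation from the unique peak-gene table.
#'
#' @param norm An `"expr_norm"` object.
#' @param isg_genes Character vector of ISG identifiers.
#' @param mixed_cols,beta_cols,gamma_cols,basal_cols Column selections for
#'   the mixing experiment (see [select_condition()]).
#' @param gene_table Unique peak-gene table from [unique_gene_table()]
#'   (optional).
#' @param genome,tss Genome and TSS annotation for promoter GC (optional).
#' @param gc_window,pseudocount See [analysis_config()].
#' @return A data frame of class `"enhancement_records"` with one row per
#'   gene: `gene_id`, `es`, `rpkm_mixed`, `rpkm_beta`, `rpkm_gamma`,
#'   `rpkm_basal`, `quartile`, `promoter_gc`, `has_promoter_peak`,
#'   `promoter_peak_category`. The quartile thresholds are attached as the
#'   `"partition"` attribute.
#' @export
enhancement_records <- function(norm, isg_genes, mixed_cols, beta_cols,
                                gamma_cols, basal_cols, gene_table = NULL,
                                genome = NULL, tss = NULL,
                                gc_window = c(-300, 300), pseudocount = 1) {
  stopifnot(inherits(norm, "expr_norm"))
  g <- intersect(isg_genes, rownames(norm$rpkm))
  rec <- data.frame(
    gene_id = g,
    rpkm_mixed = .rpkm_mean(norm, mixed_cols)[g],
    rpkm_beta = .rpkm_mean(norm, beta_cols)[g],
    rpkm_gamma = .rpkm_mean(norm, gamma_cols)[g],
    rpkm_basal = .rpkm_mean(norm, basal_cols)[g],
    stringsAsFactors = FALSE
  )
  rec$es <- enhancement_score(rec$rpkm_mixed, rec$rpkm_beta, rec$rpkm_gamma,
                              pseudocount)
  part <- quartile_partition(rec$es, rec$gene_id)
  rec$quartile <- part$assignment$quartile
  rec$promoter_gc <- NA_real_
  if (!is.null(genome) && !is.null(tss)) {
    t2 <- tss[match(rec$gene_id, tss$gene_id), , drop = FALSE]
    known <- !is.na(t2$gene_id)
    if (any(known)) {
      gcv <- promoter_gc(genome, t2[known, , drop = FALSE], gc_window)
      rec$promoter_gc[known] <- gcv$gc
    }
  }
  rec$has_promoter_peak <- FALSE
  rec$promoter_peak_category <- NA_character_
  if (!is.null(gene_table)) {
    m <- match(rec$gene_id, gene_table$gene_id)
    hit <- !is.na(m) & gene_table$promoter[ifelse(is.na(m), 1L, m)]
    rec$has_promoter_peak <- !is.na(m) & hit
    rec$promoter_peak_category[rec$has_promoter_peak] <-
      gene_table$category[m[rec$has_promoter_peak]]
  }
  attr(rec, "partition") <- part
  class(rec) <- c("enhancement_records", "data.frame")
  rec
}

#' Compare top and bottom enhancement quartiles
#'
#' Two-sided rank-sum tests for the continuous covariates (basal RPKM,
#' promoter GC) and a two-sided Fisher exact test for the promoter-peak
#' 2x2 table, with all fractions reported alongside p-values.
#'
#' @param records An `"enhancement_records"` data frame.
#' @return A list of class `"quartile_comparison"`: `basal` (test +
#'   medians), `gc` (test + medians), `promoter_peak` (test, counts and
#'   nearest-integer percents).
#' @export
compare_quartiles <- function(records) {
  top <- records[records$quartile == "TOP", , drop = FALSE]
  bot <- records[records$quartile == "BOTTOM", , drop = FALSE]
  if (nrow(top) == 0L || nrow(bot) == 0L)
    stop("compare_quartiles: both quartiles must be non-empty")
  basal <- list(
    test = rank_sum_test(top$rpkm_basal, bot$rpkm_basal),
    median_top = stats::median(top$rpkm_basal),
    median_bottom = stats::median(bot$rpkm_basal)
  )
  gc <- NULL
  if (!all(is.na(top$promoter_gc)) && !all(is.na(bot$promoter_gc))) {
    gc <- list(
      test = rank_sum_test(top$promoter_gc[!is.na(top$promoter_gc)],
                           bot$promoter_gc[!is.na(bot$promoter_gc)]),
      median_top = stats::median(top$promoter_gc, na.rm = TRUE),
      median_bottom = stats::median(bot$promoter_gc, na.rm = TRUE)
    )
  }
  tab <- matrix(c(sum(top$has_promoter_peak), sum(!top$has_promoter_peak),
                  sum(bot$has_promoter_peak), sum(!bot$has_promoter_peak)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("TOP", "BOTTOM"), c("promoter", "no_promoter")))
  pp <- list(
    test = fisher_exact(tab),
    table = tab,
    count_top = sum(top$has_promoter_peak), n_top = nrow(top),
    count_bottom = sum(bot$has_promoter_peak), n_bottom = nrow(bot),
    percent_top = round(100 * mean(top$has_promoter_peak)),
    percent_bottom = round(100 * mean(bot$has_promoter_peak))
  )
  structure(list(basal = basal, gc = gc, promoter_peak = pp),
            class = "quartile_comparison")
}

#' @export
print.quartile_comparison <- function(x, ...) {
  cat("Top vs bottom enhancement quartiles\n")
  cat(sprintf("  basal RPKM: median top %.2f vs bottom %.2f, rank-sum p = %.3g\n",
              x$basal$median_top, x$basal$median_bottom, x$basal$test$p_value))
  if (!is.null(x$gc))
    cat(sprintf("  promoter GC: median top %.3f vs bottom %.3f, rank-sum p = %.3g\n",
                x$gc$median_top, x$gc$median_bottom, x$gc$test$p_value))
  cat(sprintf("  promoter peak: %d/%d (%d%%) top vs %d/%d (%d%%) bottom, Fisher p = %.3g\n",
              x$promoter_peak$count_top, x$promoter_peak$n_top,
              x$promoter_peak$percent_top, x$promoter_peak$count_bottom,
              x$promoter_peak$n_bottom, x$promoter_peak$percent_bottom,
              x$promoter_peak$test$p_value))
  invisible(x)
}

#' Enhancement scores by promoter motif class
#'
#' Among genes with promoter peaks, compares the Enhancement-score
#' distributions of genes whose promoter peak carries BOTH motifs against
#' genes whose promoter peak carries only the ISRE motif, with a one-sided
#' rank-sum test (BOTH > ISRE).
#'
#' @param records An `"enhancement_records"` data frame.
#' @return A list with per-group `es` values, `median_both`, `median_isre`,
#'   `test` (an `"ifn_test"`), or `skipped = TRUE` with a reason when a
#'   group is empty.
#' @export
es_by_promoter_motif <- function(records) {
  pp <- records[records$has_promoter_peak, , drop = FALSE]
  es_both <- pp$es[pp$promoter_peak_category == "BOTH"]
  es_isre <- pp$es[pp$promoter_peak_category == "ISRE"]
  if (length(es_both) == 0L || length(es_isre) == 0L) {
    return(list(skipped = TRUE,
                reason = "empty BOTH or ISRE promoter-peak group",
                n_both = length(es_both), n_isre = length(es_isre)))
  }
  list(skipped = FALSE, es_both = es_both, es_isre = es_isre,
       median_both = stats::median(es_both),
       median_isre = stats::median(es_isre),
       test = rank_sum_test(es_both, es_isre, alternative = "greater"))
}
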