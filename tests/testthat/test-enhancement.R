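test_that("enhancement scores follow the per-term pseudocount convention", {
  expect_equal(enhancement_score(0, 0, 0), 0.5)
  expect_equal(enhancement_score(3, 1, 1), 1)
  expect_equal(enhancement_score(7, 1, 1), 2)
  expect_equal(enhancement_score(c(3, 7), c(1, 1), c(1, 1)), c(1, 2))
  expect_error(enhancement_score(-1, 0, 0))
})

test_that("quartile partition sizes are ceiling(n/4) with ordered tails", {
  set.seed(11)
  s179 <- sample(seq(0.2, 3, length.out = 179))
  part <- quartile_partition(s179, sprintf("g%03d", 1:179))
  expect_equal(part$q, 45)
  tab <- table(part$assignment$quartile)
  expect_equal(as.integer(tab[c("TOP", "BOTTOM")]), c(45L, 45L))
  a <- part$assignment
  expect_true(min(a$score[a$quartile == "TOP"]) >=
                max(a$score[a$quartile == "MID"]))
  expect_true(min(a$score[a$quartile == "MID"]) >=
                max(a$score[a$quartile == "BOTTOM"]))
  expect_equal(part$top_threshold, min(a$score[a$quartile == "TOP"]))
  expect_equal(quartile_partition(1:8, letters[1:8])$q, 2)
  expect_equal(quartile_partition(1:4, letters[1:4])$q, 1)
  expect_error(quartile_partition(1:3, letters[1:3]), "at least 4")
  expect_error(quartile_partition(c(1, 2, Inf, 4), letters[1:4]), "finite")
})

test_that("tied quartile boundaries resolve deterministically by gene id", {
  part <- quartile_partition(rep(1, 8), letters[1:8])
  a <- part$assignment
  expect_equal(a$gene_id[a$quartile == "TOP"], c("a", "b"))
  expect_equal(a$gene_id[a$quartile == "BOTTOM"], c("g", "h"))
})

test_that("GC content counts G+C over unambiguous bases", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("ACGN"), 2 / 3)  # N excluded from both sides
  expect_true(is.na(gc_content("NNNN")))
  set.seed(5)
  s <- random_seq(400)
  expect_equal(gc_content(s), gc_content(oracle_revcomp(s)))
})

test_that("promoter GC windows are strand-agnostic and clipped at bounds", {
  g <- Biostrings::DNAStringSet(c(chr = paste0(strrep("A", 500),
                                               strrep("G", 100),
                                               strrep("A", 500))))
  tss <- data.frame(gene_id = c("mid", "edge"), chrom = "chr",
                    tss = c(550L, 10L), strand = c("+", "-"))
  gc <- promoter_gc(g, tss, c(-300, 300))
  expect_equal(gc$gc[1], 100 / 600, tolerance = 1e-9)
  expect_false(gc$clipped[1])
  expect_true(gc$clipped[2])
  # strand makes no difference
  tssm <- tss; tssm$strand <- c("-", "+")
  expect_equal(promoter_gc(g, tssm, c(-300, 300))$gc, gc$gc)
})

test_that("quartile comparison reports fractions with the three tests", {
  rec <- data.frame(
    gene_id = sprintf("g%02d", 1:20),
    es = c(seq(2, 1.5, length.out = 5), seq(1.2, 0.9, length.out = 10),
           seq(0.7, 0.5, length.out = 5)),
    rpkm_basal = c(rep(2, 5), rep(10, 10), rep(50, 5)),
    promoter_gc = c(rep(0.4, 5), rep(0.5, 10), rep(0.6, 5)),
    has_promoter_peak = c(rep(TRUE, 4), rep(FALSE, 12), rep(TRUE, 1),
                          rep(FALSE, 3)),
    stringsAsFactors = FALSE)
  rec$quartile <- quartile_partition(rec$es, rec$gene_id)$assignment$quartile
  cmp <- compare_quartiles(rec)
  expect_equal(cmp$promoter_peak$count_top, 4)
  expect_equal(cmp$promoter_peak$percent_top, 80)
  expect_equal(cmp$promoter_peak$percent_bottom, 20)
  expect_lt(cmp$basal$test$p_value, 0.05)
  expect_lt(cmp$gc$test$p_value, 0.05)
  expect_equal(round(100 * 25 / 45), 56)  # reported as nearest-integer percent
  expect_equal(round(100 * 10 / 45), 22)
})

test_that("identical quartile groups show no difference", {
  rec <- data.frame(
    gene_id = sprintf("g%02d", 1:8),
    es = 8:1,
    rpkm_basal = rep(3, 8),
    promoter_gc = rep(0.5, 8),
    has_promoter_peak = rep(c(TRUE, FALSE), 4),
    quartile = c("TOP", "TOP", rep("MID", 4), "BOTTOM", "BOTTOM"),
    stringsAsFactors = FALSE)
  cmp <- compare_quartiles(rec)
  expect_gte(cmp$basal$test$p_value, 0.99)
  expect_gte(cmp$gc$test$p_value, 0.99)
  expect_gte(cmp$promoter_peak$test$p_value, 0.99)
})

test_that("ES by promoter motif class separates planted BOTH from ISRE genes", {
  set.seed(31)
  n <- 40
  rec <- data.frame(
    gene_id = sprintf("g%02d", 1:(2 * n)),
    es = c(rnorm(n, 2, 0.2), rnorm(n, 1, 0.2)),
    has_promoter_peak = TRUE,
    promoter_peak_category = rep(c("BOTH", "ISRE"), each = n),
    stringsAsFactors = FALSE)
  res <- es_by_promoter_motif(rec)
  expect_false(res$skipped)
  expect_gt(res$median_both, res$median_isre)
  expect_lt(res$test$p_value, 0.05)
  # single gene per group: exact one-sided p is 1/2
  res1 <- es_by_promoter_motif(rec[c(1, n + 1), ])
  expect_equal(res1$test$p_value, 0.5)
  # an empty group skips the comparison with a flag
  res0 <- es_by_promoter_motif(rec[rec$promoter_peak_category == "BOTH", ])
  expect_true(res0$skipped)
})

test_that("null ES comparisons yield calibrated one-sided p-values", {
  set.seed(77)
  n_sims <- 200
  pvals <- replicate(n_sims, {
    es <- rnorm(24, 1, 0.3)
    rec <- data.frame(gene_id = sprintf("g%02d", 1:24), es = es,
                      has_promoter_peak = TRUE,
                      promoter_peak_category = rep(c("BOTH", "ISRE"), 12),
                      stringsAsFactors = FALSE)
    es_by_promoter_motif(rec)$test$p_value
  })
  # under the null the one-sided p is approximately uniform
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(mean(pvals), 0.4)
  expect_lt(mean(pvals), 0.6)
})
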