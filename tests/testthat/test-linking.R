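mk_tss <- function(...) {
  df <- data.frame(...)
  df[c("gene_id", "chrom", "tss", "strand")]
}

test_that("peak reference point is the summit or the floored midpoint", {
  expect_equal(peak_reference_point(data.frame(start = 100, end = 300)), 200L)
  expect_equal(peak_reference_point(data.frame(start = 100, end = 301)), 200L)
  expect_equal(
    peak_reference_point(data.frame(start = 100, end = 300, summit = 250)), 250L)
  expect_equal(
    peak_reference_point(data.frame(start = c(0, 10), end = c(10, 21),
                                    summit = c(NA, 12))), c(5L, 12L))
})

test_that("links are strand-aware with the inclusive promoter window", {
  tss <- mk_tss(gene_id = c("gPlus", "gMinus"), chrom = "chr1",
                tss = c(5000L, 20000L), strand = c("+", "-"))
  peaks <- data.frame(
    chrom = "chr1",
    start = c(4900, 20400, 2900, 19090, 5100),
    end = c(5100, 20600, 3100, 19110, 5300),
    peak = c("at_tss", "minus_up500", "far_up", "minus_down900", "edge"))
  links <- link_peaks(peaks, tss)
  expect_equal(links$signed_distance[links$peak == "at_tss"], 0)
  expect_true(links$promoter[links$peak == "at_tss"])
  # 500 bp 5' of a minus-strand TSS sits at TSS+500 in genome coordinates
  expect_equal(links$gene_id[links$peak == "minus_up500"], "gMinus")
  expect_equal(links$signed_distance[links$peak == "minus_up500"], -500)
  expect_true(links$promoter[links$peak == "minus_up500"])
  # 2100 bp upstream: linked but not a promoter peak
  expect_equal(links$gene_id[links$peak == "far_up"], "gPlus")
  expect_false(links$promoter[links$peak == "far_up"])
  # minus strand, 900 bp downstream in gene orientation -> +900, distal
  expect_equal(links$signed_distance[links$peak == "minus_down900"], 900)
  expect_false(links$promoter[links$peak == "minus_down900"])
  # +100 boundary is inclusive
  expect_equal(links$signed_distance[links$peak == "edge"], 200)
  expect_false(links$promoter[links$peak == "edge"])
})

test_that("promoter window bounds are inclusive at -1000 and +100", {
  tss <- mk_tss(gene_id = "g", chrom = "c", tss = 10000L, strand = "+")
  pk <- function(ref) data.frame(chrom = "c", start = ref - 100, end = ref + 100,
                                 peak = "p")
  expect_true(link_peaks(pk(9000), tss)$promoter)    # exactly -1000
  expect_true(link_peaks(pk(10100), tss)$promoter)   # exactly +100
  expect_false(link_peaks(pk(8999), tss)$promoter)
  expect_false(link_peaks(pk(10101), tss)$promoter)
})

test_that("peaks on chromosomes without expressed genes are unassigned", {
  tss <- mk_tss(gene_id = "g", chrom = "chr1", tss = 100L, strand = "+")
  peaks <- data.frame(chrom = c("chr1", "chr9"), start = c(0, 0),
                      end = c(50, 50), peak = c("a", "b"))
  links <- link_peaks(peaks, tss)
  expect_equal(links$unassigned, c(FALSE, TRUE))
  # restricting the expressed set removes candidates
  links2 <- link_peaks(peaks, tss, expressed = character(0))
  expect_true(all(links2$unassigned))
})

test_that("nearest-gene choice breaks ties lexicographically", {
  tss <- mk_tss(gene_id = c("gB", "gA"), chrom = "c",
                tss = c(900L, 1100L), strand = "+")
  pk <- data.frame(chrom = "c", start = 900, end = 1100, peak = "mid")
  expect_equal(link_peaks(pk, tss)$gene_id, "gA")  # equidistant: gA < gB
})

test_that("one link per gene: promoter precedence, then nearest", {
  links <- data.frame(
    peak = c("p_dist", "p_prom", "q5k", "q3k", "solo"),
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    signed_distance = c(3000, -200, 5000, 3000, 10),
    distance = c(3000, 200, 5000, 3000, 10),
    promoter = c(FALSE, TRUE, FALSE, FALSE, TRUE),
    category = c("GAS", "ISRE", "GAS", "GAS", "BOTH"),
    unassigned = FALSE, stringsAsFactors = FALSE)
  tab <- unique_gene_table(links)
  expect_equal(nrow(tab), 3)
  # promoter ISRE link beats the nearer... the distal GAS link
  expect_equal(tab$peak[tab$gene_id == "g1"], "p_prom")
  expect_equal(tab$category[tab$gene_id == "g1"], "ISRE")
  expect_equal(tab$peak[tab$gene_id == "g2"], "q3k")
  expect_equal(tab$n_peaks, c(2L, 2L, 1L))
})

test_that("linkage recovers planted peak-gene truth on synthetic data", {
  sim <- small_sim()
  run <- small_run()
  tg <- sim$rna$truth_genes
  gt <- run$gene_table
  planted <- tg[!is.na(tg$linked_peak) & tg$gene_id %in% gt$gene_id, ]
  expect_equal(gt$peak[match(planted$gene_id, gt$gene_id)], planted$linked_peak)
  expect_lte(nrow(gt), nrow(run$links))
})

test_that("promoter flags are invariant under genome translation", {
  tss <- mk_tss(gene_id = c("g1", "g2"), chrom = "c",
                tss = c(5000L, 9000L), strand = c("+", "-"))
  peaks <- data.frame(chrom = "c", start = c(4400, 9100), end = c(4600, 9300),
                      peak = c("a", "b"))
  base <- link_peaks(peaks, tss)
  shift <- 12345L
  tss2 <- tss; tss2$tss <- tss2$tss + shift
  peaks2 <- peaks
  peaks2$start <- peaks2$start + shift
  peaks2$end <- peaks2$end + shift
  moved <- link_peaks(peaks2, tss2)
  expect_equal(moved$promoter, base$promoter)
  expect_equal(moved$signed_distance, base$signed_distance)
})

test_that("distance distributions report per-category medians", {
  links <- data.frame(peak = letters[1:5], gene_id = paste0("g", 1:5),
                      signed_distance = c(0, 100, -4000, 2500, 3000),
                      distance = c(0, 100, 4000, 2500, 3000),
                      promoter = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                      category = c("ISRE", "ISRE", "GAS", "GAS", "GAS"),
                      unassigned = FALSE, stringsAsFactors = FALSE)
  dd <- distance_distribution(links)
  expect_equal(dd$medians[["ISRE"]], 50)
  expect_equal(dd$medians[["GAS"]], 3000)
  expect_gt(dd$medians[["GAS"]], dd$medians[["ISRE"]])
  one <- distance_distribution(links[1, ])
  expect_equal(lengths(one$distances)[["ISRE"]], 1L)
})
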