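test_that("largest-remainder allocation reproduces the printed category sizes", {
  props <- simulation_params()$category_proportions
  alloc <- ifnsynergy:::.largest_remainder(723, props)
  expect_equal(unname(alloc), c(280L, 201L, 155L, 87L))
  expect_equal(names(alloc), c("GAS", "ISRE", "BOTH", "NO_MOTIF"))
  expect_equal(sum(ifnsynergy:::.largest_remainder(100, c(1, 1, 1))), 100L)
  expect_equal(unname(ifnsynergy:::.largest_remainder(10, c(GAS = 1, ISRE = 0))),
               c(10L, 0L))
})

test_that("zero-GC backgrounds use only A and T", {
  p <- simulation_params(n_peaks = 8, n_background_peaks = 0, n_genes = 30,
                         n_isgs = 4, n_multipeak_genes = 0, gc_background = 0,
                         gc_targets = c(synergy = 0, redundant = 0), seed = 3)
  g <- simulate_genome(p)
  chars <- unique(strsplit(as.character(g$sequences[["chr2"]]), "")[[1]])
  expect_true(all(chars %in% c("A", "T")))
})

test_that("background GC concentrates near its target on long sequences", {
  p <- simulation_params(n_peaks = 10, n_background_peaks = 0, n_genes = 160,
                         n_isgs = 4, n_multipeak_genes = 0, gc_background = 0.5,
                         bg_gene_spacing = 700, seed = 4)
  g <- simulate_genome(p)
  s <- as.character(g$sequences[["chr2"]])  # > 100 kb of background
  expect_gte(nchar(s), 1e5)
  gc <- gc_content(s)
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)
})

test_that("the non-peak background contains no motif-family match on either strand", {
  sim <- small_sim()
  g <- sim$genome
  chars <- strsplit(as.character(g$sequences[["chr1"]]), "")[[1]]
  for (i in seq_len(nrow(g$peaks))) {  # mask planted peak intervals
    chars[(g$peaks$start[i] + 1):g$peaks$end[i]] <- "N"
  }
  masked <- paste(chars, collapse = "")
  for (mo in default_motifs()) {
    expect_equal(nrow(scan_motif(masked, mo)), 0)
  }
  for (mo in default_motifs()) {  # chr2 carries no peaks at all
    expect_equal(nrow(scan_motif(as.character(g$sequences[["chr2"]]), mo)), 0)
  }
})

test_that("planted motif content matches each peak's category exactly", {
  sim <- small_sim()
  cl <- classify_peaks(sim$genome$peaks, sim$genome$sequences)
  truth <- sim$chip$truth_peaks
  expect_equal(cl$category, truth$category[match(cl$peak, truth$peak)])
})

test_that("the generator is byte-identical under a fixed seed", {
  p <- simulation_params(n_peaks = 12, n_background_peaks = 4, n_genes = 60,
                         n_isgs = 8, n_multipeak_genes = 2, seed = 99)
  s1 <- simulate_dataset(p)
  s2 <- simulate_dataset(p)
  expect_identical(as.character(s1$genome$sequences), as.character(s2$genome$sequences))
  expect_identical(s1$chip$signal, s2$chip$signal)
  expect_identical(s1$rna$counts, s2$rna$counts)
  expect_identical(s1$rna$truth_genes, s2$rna$truth_genes)
  p3 <- simulation_params(n_peaks = 12, n_background_peaks = 4, n_genes = 60,
                          n_isgs = 8, n_multipeak_genes = 2, seed = 100)
  s3 <- simulate_dataset(p3)
  expect_false(identical(s1$chip$signal, s3$chip$signal))
})

test_that("noiseless ChIP signal reproduces planted folds exactly", {
  sim <- noiseless_small_sim()
  sig <- sim$chip$signal
  fold <- sim$chip$planted_fold
  basal <- sig[, "basal_0U_0h_r1"]
  expect_equal(sig / basal, fold, tolerance = 1e-12)
  # planted inducible flags equal the rule applied to planted folds
  got <- find_inducible(sig, fold = 2, min_timepoints = 2, pseudocount = 1e-9)
  expect_equal(unname(got), unname(sim$chip$truth_peaks$inducible))
})

test_that("dose gating nulls GAS-class induction below the gate", {
  sim <- noiseless_small_sim()
  tp <- sim$chip$truth_peaks
  fold <- sim$chip$planted_fold
  low_cols <- grep("^beta_1U", colnames(fold), value = TRUE)
  high_cols <- grep("^beta_10U", colnames(fold), value = TRUE)
  gas <- tp$peak[tp$category == "GAS" & tp$inducible_design]
  expect_true(all(fold[gas, low_cols] == 1))
  expect_true(all(apply(fold[gas, high_cols], 1, max) >= 2))
  isre <- tp$peak[tp$category == "ISRE" & tp$inducible_design]
  expect_equal(fold[isre, low_cols], fold[isre, high_cols],
               ignore_attr = TRUE)
})

test_that("expression plan: epithelial silence, synergy formula, noiseless counts", {
  sim <- noiseless_small_sim()
  tg <- sim$rna$truth_genes
  gas_linked <- tg[!is.na(tg$link_category) & tg$link_category == "GAS", ]
  expect_gt(nrow(gas_linked), 0)
  expect_true(all(gas_linked$fold_beta_low == 1))
  expect_true(all(gas_linked$fold_beta_high == 1))  # epithelial mode
  expect_false(any(gas_linked$isg))
  syn <- tg[!is.na(tg$mix_mode) & tg$mix_mode == "synergy", ]
  expect_true(all(abs(syn$rpkm_mixed -
                        2 * (syn$rpkm_beta_low + syn$rpkm_gamma_low)) < 1e-9))
  # noiseless counts equal the planted expected CPM scaled by library size
  # (integer rounding only), consistently across the stored truth tables
  lib <- sim$rna$lib_sizes
  exp_cpm <- sim$rna$expected_rpkm * (tg$length / 1e3)
  mu <- exp_cpm[, "basal"] * lib[["basal_0U_0h_r1"]] / 1e6
  expect_equal(unname(sim$rna$counts[, "basal_0U_0h_r1"]), unname(round(mu)))
  mu_mix <- exp_cpm[, "mixed"] * lib[["mixed_1U_4h_r2"]] / 1e6
  expect_equal(unname(sim$rna$counts[, "mixed_1U_4h_r2"]), unname(round(mu_mix)))
})

test_that("macrophage mode induces GAS-linked genes", {
  p <- simulation_params(n_peaks = 80, n_background_peaks = 0, n_genes = 300,
                         n_isgs = 40, n_multipeak_genes = 5,
                         mode = "macrophage", chip_noise_sigma = 0,
                         nb_dispersion = 0, seed = 17)
  sim <- simulate_dataset(p)
  tg <- sim$rna$truth_genes
  gas_linked <- tg[!is.na(tg$link_category) & tg$link_category == "GAS", ]
  expect_gt(mean(gas_linked$fold_beta_high > 2), 0.4)
  expect_gt(sum(gas_linked$isg), 0)
})

test_that("simulated datasets write plain-text artifacts that read back", {
  dir <- withr::local_tempdir()
  p <- simulation_params(n_peaks = 10, n_background_peaks = 2, n_genes = 50,
                         n_isgs = 6, n_multipeak_genes = 1, seed = 23)
  sim <- simulate_dataset(p, dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("genome.fa", "peaks.bed", "chip_signal.tsv", "counts.tsv",
      "gene_lengths.tsv", "tss.tsv", "truth_peaks.tsv", "truth_genes.tsv")))))
  peaks <- read_bed(file.path(dir, "peaks.bed"))
  expect_equal(peaks$peak, sim$genome$peaks$peak)
  sig <- read_matrix(file.path(dir, "chip_signal.tsv"))
  expect_equal(dim(sig), dim(sim$chip$signal))
  expect_equal(unname(sig[, ]), unname(sim$chip$signal[, ]), tolerance = 1e-9)
  tss <- read_tss(file.path(dir, "tss.tsv"))
  expect_equal(nrow(tss), 50)
})

test_that("truth labels cover every peak and gene with planted sites inside peaks", {
  sim <- small_sim()
  tp <- sim$chip$truth_peaks
  tg <- sim$rna$truth_genes
  expect_false(any(is.na(tp$category)))
  expect_false(any(is.na(tp$inducible)))
  expect_false(any(is.na(tg$isg)))
  expect_equal(sort(tp$peak), sort(sim$genome$peaks$peak))
  expect_equal(sort(tg$gene_id), sort(sim$genome$tss$gene_id))
  # category proportions allocated over the inducible peaks
  expect_equal(sum(tp$inducible_design), sim$params$n_peaks)
})
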