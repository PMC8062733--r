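gas_probe <- "TACAACAGCCTGATTTCCCCGAAATGACGC"
isre_probe <- "GATCCTCGGGAAAGGGAAACCTAAACTGAAGCC"
irf1_variant <- "GATTTCCCCGAATG"

test_that("motif compilation derives lengths and rejects malformed specs", {
  gas <- compile_motif("TTCN{2,4}GAA", "GAS_family")
  expect_equal(gas$min_length, 8)
  expect_equal(gas$max_length, 10)
  expect_equal(gas$blocks, c("TTC", "GAA"))
  isre <- compile_motif("AGTTTCN{2}TTTC", "ISRE_family")
  expect_equal(isre$min_length, 12)
  expect_equal(isre$max_length, 12)
  fixed <- compile_motif(irf1_variant, "GAS_family")
  expect_equal(fixed$min_length, 14)
  expect_equal(length(fixed$spacer_min), 0)
  expect_error(compile_motif("TTCN{4,2}GAA", "GAS_family"), "min > max")
  expect_error(compile_motif("TTCN{2,4}", "GAS_family"), "fixed block")
  expect_error(compile_motif("TTQGAA", "GAS_family"), "IUPAC")
})

test_that("the GAS EMSA probe carries a canonical GAS site at offset 14", {
  gas <- default_motifs()$GAS
  hits <- scan_motif(gas_probe, gas)
  fwd <- hits[hits$strand == "+", ]
  expect_gte(nrow(hits), 1)
  expect_true(any(fwd$offset == 14 & fwd$spacer == 3))
})

test_that("the Irf1 variant sequence yields GAS-family matches", {
  g <- Biostrings::DNAStringSet(c(probe = gas_probe, variant = irf1_variant))
  peaks <- data.frame(chrom = c("probe", "variant"), start = 0,
                      end = c(nchar(gas_probe), nchar(irf1_variant)),
                      peak = c("p1", "p2"))
  cl <- classify_peaks(peaks, g)
  expect_true(all(cl$gas_hits >= 1))
  expect_equal(cl$category, c("GAS", "GAS"))
  # the variant embeds a canonical TTC-spacer-GAA element as well
  expect_gte(nrow(scan_motif(irf1_variant, default_motifs()$GAS)), 1)
})

test_that("the ISRE EMSA probe carries the ISRE core on the reverse strand
           but not the full strict consensus", {
  isre <- default_motifs()$ISRE
  expect_equal(nrow(scan_motif(isre_probe, isre, both_strands = TRUE)), 0)
  core <- compile_motif("TTTCN{2}TTTC", "ISRE_family", name = "ISRE_core")
  hits <- scan_motif(isre_probe, core, both_strands = TRUE)
  expect_gte(sum(hits$strand == "-"), 1)
})

test_that("consensus scanning equals brute-force enumeration on random sequences", {
  set.seed(515)
  gas <- default_motifs()$GAS
  isre <- default_motifs()$ISRE
  for (i in 1:200) {
    s <- random_seq(200, c("A", "C", "G", "T", if (i %% 5 == 0) "N"))
    for (mo in list(gas, isre)) {
      got <- scan_motif(s, mo)
      want <- oracle_scan(s, mo$blocks, mo$spacer_min, mo$spacer_max)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        expect_equal(got$offset, unname(want[, "offset"]))
        expect_equal(got$length, unname(want[, "length"]))
        expect_equal(got$strand, c("+", "-")[want[, "strand_code"]])
      }
    }
  }
})

test_that("matches are strand-symmetric under reverse complement", {
  set.seed(616)
  gas <- default_motifs()$GAS
  for (i in 1:30) {
    s <- random_seq(150)
    rc <- oracle_revcomp(s)
    fwd_on_s <- scan_motif(s, gas)
    fwd_on_rc <- scan_motif(rc, gas)
    minus <- fwd_on_s[fwd_on_s$strand == "-", ]
    plus_rc <- fwd_on_rc[fwd_on_rc$strand == "+", ]
    # reflect coordinates of + matches on the reverse complement
    reflected <- sort(nchar(s) - (plus_rc$offset + plus_rc$length))
    expect_equal(sort(minus$offset), reflected)
  }
})

test_that("poly-A and N-containing windows never match", {
  for (mo in default_motifs()) {
    expect_equal(nrow(scan_motif("AAAAAAAAAAAA", mo)), 0)
  }
  # an N inside an otherwise perfect site kills the match
  expect_equal(nrow(scan_motif("TTCNNGAA", default_motifs()$GAS)), 0)
  expect_gte(nrow(scan_motif("TTCAGGAA", default_motifs()$GAS)), 1)
})

test_that("hit counts map to the four peak categories", {
  expect_equal(categorize_peak(c(3, 0, 1, 0), c(0, 2, 1, 0)),
               c("GAS", "ISRE", "BOTH", "NO_MOTIF"))
  expect_error(categorize_peak(-1, 0), ">= 0")
  expect_error(categorize_peak(c(1, 2), c(0)), "equal length")
})

test_that("cross-genotype TF presence categorization follows the stated rules", {
  expect_equal(categorize_by_tf_presence(TRUE, FALSE, TRUE, TRUE), "GAF")
  expect_equal(categorize_by_tf_presence(FALSE, TRUE, FALSE, FALSE), "ISGF3")
  expect_equal(categorize_by_tf_presence(TRUE, TRUE, TRUE, FALSE), "OTHER")
  expect_equal(categorize_by_tf_presence(TRUE, TRUE, FALSE, FALSE), "ISGF3")
  expect_equal(categorize_by_tf_presence(FALSE, FALSE, FALSE, FALSE), "OTHER")
  expect_equal(
    categorize_by_tf_presence(c(TRUE, FALSE), c(FALSE, TRUE),
                              c(FALSE, FALSE), c(FALSE, FALSE)),
    c("GAF", "ISGF3"))
})

test_that("PWM mode recovers its consensus at the threshold", {
  # a sharp PWM for TTCA: only the exact word reaches the maximum score
  pwm <- matrix(0.01, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm["T", 1] <- 0.97; pwm["T", 2] <- 0.97
  pwm["C", 3] <- 0.97; pwm["A", 4] <- 0.97
  pwm <- sweep(pwm, 2, colSums(pwm), "/")
  mo <- pwm_motif(pwm, "GAS_family", threshold = 4 * log2(0.97 / 0.25) - 0.1)
  hits <- scan_motif("GGTTCAGG", mo, both_strands = FALSE)
  expect_equal(hits$offset, 2)
  # N inside the window disqualifies it
  expect_equal(nrow(scan_motif("GGTTNAGG", mo, both_strands = FALSE)), 0)
  # a permissive threshold admits near-matches
  mo2 <- pwm_motif(pwm, "GAS_family", threshold = 0)
  expect_gte(nrow(scan_motif("GGTTCAGG", mo2, both_strands = FALSE)), 1)
  expect_error(pwm_motif(pwm * 2, "GAS_family", 1), "sum to 1")
})

test_that("deterministic match ordering: position, then strand, then spacer", {
  gas <- default_motifs()$GAS
  # TTCAAGAAGAA has overlapping spacer-2 and spacer-5(no) matches
  hits <- scan_motif("TTCAAGAATTCAAAAGAA", gas)
  expect_false(is.unsorted(hits$offset))
  same_pos <- split(hits, hits$offset)
  for (h in same_pos) {
    if (nrow(h) > 1) {
      expect_false(is.unsorted(match(h$strand, c("+", "-"))))
    }
  }
})
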