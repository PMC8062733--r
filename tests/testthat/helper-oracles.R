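# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no regexes, no stats::wilcox.test/fisher.test) so that
# agreement is a genuine two-route check.

iupac_table <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# enumerate every offset, spacer combination and strand by direct
# character comparison
oracle_scan <- function(seq, blocks, smin, smax, both_strands = TRUE) {
  scan_strand <- function(s) {
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    hits <- list()
    spacers <- if (length(smin)) smin:smax else 0L
    for (sp in spacers) {
      pat <- if (length(smin))
        c(strsplit(blocks[1], "")[[1]], rep("N", sp), strsplit(blocks[2], "")[[1]])
      else strsplit(blocks[1], "")[[1]]
      L <- length(pat)
      if (L > n) next
      for (off in 0:(n - L)) {
        okay <- TRUE
        for (k in seq_len(L)) {
          subj <- chars[off + k]
          if (subj == "N" || !(subj %in% iupac_table[[pat[k]]])) {
            okay <- FALSE
            break
          }
        }
        if (okay) hits[[length(hits) + 1L]] <- c(off, L, sp)
      }
    }
    if (length(hits)) do.call(rbind, hits) else
      matrix(integer(0), ncol = 3)
  }
  fwd <- scan_strand(seq)
  out <- if (nrow(fwd)) cbind(fwd, 1L) else matrix(integer(0), ncol = 4)
  if (both_strands) {
    rc <- scan_strand(oracle_revcomp(seq))
    if (nrow(rc)) {
      rc[, 1] <- nchar(seq) - (rc[, 1] + rc[, 2])
      out <- rbind(out, cbind(rc, 2L))
    }
  }
  colnames(out) <- c("offset", "length", "spacer", "strand_code")
  out[order(out[, 1], out[, 4], out[, 2]), , drop = FALSE]
}

# exact rank-sum p by full enumeration over rank assignments
oracle_ranksum <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  all_w <- apply(utils::combn(n, n1), 2, function(idx) sum(r[idx]))
  mu <- mean(all_w)
  switch(alternative,
    greater = mean(all_w >= w_obs),
    less = mean(all_w <= w_obs),
    two.sided = min(1, 2 * min(mean(all_w >= w_obs), mean(all_w <= w_obs)))
  )
}

# Fisher exact by direct enumeration of all tables with the observed margins
oracle_fisher <- function(tab, alternative = "two.sided") {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(a_range, function(a) {
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  }, 0)
  a_obs <- tab[1, 1]
  p_obs <- probs[a_range == a_obs]
  switch(alternative,
    greater = sum(probs[a_range >= a_obs]),
    less = sum(probs[a_range <= a_obs]),
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)])
  )
}

# step-up BH by the defining formula: min over j >= rank(i) of (m/j) p_(j)
oracle_bh <- function(p) {
  m <- length(p)
  ps <- sort(p)
  adj_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  pmin(1, adj_sorted)[rank(p, ties.method = "first")]
}

# shared small synthetic dataset, built once per test session
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    p <- simulation_params(n_peaks = 60, n_background_peaks = 15,
                           n_genes = 300, n_isgs = 40,
                           n_multipeak_genes = 8, seed = 421)
    .fixture_env$sim <- simulate_dataset(p)
  }
  .fixture_env$sim
}

small_run <- function() {
  if (is.null(.fixture_env$run)) {
    .fixture_env$run <- run_ifn_pipeline(small_sim())
  }
  .fixture_env$run
}

noiseless_small_sim <- function() {
  if (is.null(.fixture_env$sim0)) {
    p <- simulation_params(n_peaks = 60, n_background_peaks = 15,
                           n_genes = 300, n_isgs = 40, n_multipeak_genes = 8,
                           chip_noise_sigma = 0, nb_dispersion = 0, seed = 422)
    .fixture_env$sim0 <- simulate_dataset(p)
  }
  .fixture_env$sim0
}

random_seq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}
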