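# ---- helpers ---------------------------------------------------------------

# integer allocation of n among weights by largest-remainder rounding, so
# printed proportions reproduce exactly whenever they divide n
.largest_remainder <- function(n, weights) {
  w <- weights / sum(weights)
  raw <- n * w
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

.logunif <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

# regexes whose joint absence guarantees neither motif family matches on
# either strand (the GAS pattern family is its own reverse complement; the
# Irf1 variant contains a canonical GAS instance)
.scrub_regexes <- c(
  gas = "TTC[ACGT]{2,4}GAA",
  isre_fwd = "AGTTTC[ACGT]{2}TTTC",
  isre_rev = "GAAA[ACGT]{2}GAAACT"
)

.family_present <- function(seq) {
  c(gas = grepl(.scrub_regexes["gas"], seq),
    isre = grepl(.scrub_regexes["isre_fwd"], seq) ||
      grepl(.scrub_regexes["isre_rev"], seq))
}

# draw random bases with per-position GC probability
.draw_bases <- function(pgc) {
  n <- length(pgc)
  isgc <- stats::runif(n) < pgc
  half <- stats::runif(n) < 0.5
  ifelse(isgc, ifelse(half, "G", "C"), ifelse(half, "A", "T"))
}

# resample every motif occurrence until the sequence is motif-free
.scrub_sequence <- function(chars, pgc, max_iter = 60L) {
  for (iter in seq_len(max_iter)) {
    s <- paste(chars, collapse = "")
    spans <- list()
    for (re in .scrub_regexes) {
      m <- gregexpr(re, s)[[1]]
      if (m[1] != -1L) {
        spans[[length(spans) + 1L]] <-
          cbind(as.integer(m), as.integer(m) + attr(m, "match.length") - 1L)
      }
    }
    if (length(spans) == 0L) return(chars)
    for (sp in spans) {
      for (r in seq_len(nrow(sp))) {
        idx <- sp[r, 1]:sp[r, 2]
        chars[idx] <- .draw_bases(pgc[idx])
      }
    }
  }
  stop("motif rejection sampling failed to converge; ",
       "lower gc_background or use shorter motifs")
}

.revcomp_chars <- function(x) rev(chartr("ACGT", "TGCA", x))

# ---- parameters ------------------------------------------------------------

#' Parameters of the synthetic dataset generator
#'
#' Defaults encode the study conditions the generator emulates: 723
#' inducible STAT1 peaks split 280/201/155/87 into GAS/ISRE/BOTH/no-motif
#' categories (largest-remainder allocation so the printed proportions
#' reproduce exactly), early GAS-bound and late ISGF3-bound kinetic
#' classes over a 0/0.5/1/2/4 h time course, GAS binding gated below the
#' 10 U/ml dose, 5000 genes of which 179 become interferon-stimulated
#' genes, 93 genes carrying two peaks (so the 636 motif-categorized peaks
#' collapse to 543 uniquely linked genes), and a mixing experiment in
#' which a synergy gene subset reaches `synergy_factor` times the sum of
#' the single-stimulus responses.
#'
#' @param n_peaks Number of inducible peaks.
#' @param n_background_peaks Additional non-inducible (constitutive) peaks.
#' @param peak_width Peak width in bp.
#' @param category_proportions Named weights over GAS, ISRE, BOTH,
#'   NO_MOTIF.
#' @param n_genes Total genes; `n_isgs` the size of the planted ISG panel
#'   (topped up with standalone ISGs when linked induced genes fall short).
#' @param n_isgs See `n_genes`.
#' @param n_multipeak_genes Genes hosting two motif-categorized peaks.
#' @param timepoints ChIP time course (h); the first must be 0 (basal).
#' @param doses IFN-beta doses (U/ml) for the ChIP time course.
#' @param gas_dose_gate Dose below which GAS-class (and early no-motif)
#'   peaks are not induced.
#' @param chip_replicates,rna_replicates Replicates per condition.
#' @param kinetic_params List with `early` and `late` fold profiles over
#'   `timepoints`, exponent `amp_jitter` range, and `gas_attenuation`
#'   (GAS peaks are on average induced more weakly).
#' @param basal_tags Range of basal normalized tag counts per peak.
#' @param chip_noise_sigma Lognormal sigma of multiplicative ChIP noise
#'   (0 = noiseless).
#' @param nb_dispersion Negative-binomial dispersion of RNA counts
#'   (0 = noiseless).
#' @param lib_size RNA library-size range.
#' @param gc_background Background GC fraction.
#' @param promoter_prob Per-category probability that a peak is placed in
#'   its target gene's promoter.
#' @param isg_prob Per-category, per-placement probabilities that a linked
#'   gene is induced (epithelial mode; GAS is 0).
#' @param gas_isg_prob_macrophage Replacement GAS probabilities in
#'   macrophage mode.
#' @param synergy_prob Probability that an ISG is a synergy gene, by
#'   promoter-peak class.
#' @param redundant_fraction Probability that a non-synergy ISG has a
#'   redundant (saturating, low-ES) mixed response, named by promoter-peak
#'   status (`promoter`, `distal`): weakly enhanced genes tend to lack
#'   promoter peaks.
#' @param synergy_factor Multiplier `s` on the summed single-stimulus
#'   responses for synergy genes.
#' @param isg_fold_range High-dose induction fold range for ISGs.
#' @param codriven_fold_range,driver_fold_range Single-stimulus low-dose
#'   fold ranges for synergy (co-driven) and single-driver genes.
#' @param basal_rpkm Named list of basal RPKM ranges by gene role.
#' @param gc_targets Promoter GC targets for synergy and redundant ISGs.
#' @param gene_length_range Gene length range (bp).
#' @param rna_time Timepoint (h) of the mixing-experiment RNA-seq.
#' @param promoter_offset,distal_distance Peak placement ranges relative to
#'   the TSS (bp).
#' @param block_span Genomic span reserved per linked gene (bp).
#' @param bg_gene_spacing Spacing of background genes (bp).
#' @param mode `"epithelial"` (GAS-linked genes silent) or `"macrophage"`
#'   (GAS-linked genes induced).
#' @param seed Integer seed; all outputs are byte-identical under the same
#'   seed.
#' @return A list of class `"sim_params"`.
#' @export
simulation_params <- function(n_peaks = 723,
                              n_background_peaks = 150,
                              peak_width = 200,
                              category_proportions = c(GAS = 280, ISRE = 201,
                                                       BOTH = 155, NO_MOTIF = 87),
                              n_genes = 5000,
                              n_isgs = 179,
                              n_multipeak_genes = 93,
                              timepoints = c(0, 0.5, 1, 2, 4),
                              doses = c(1, 10),
                              gas_dose_gate = 10,
                              chip_replicates = 2,
                              rna_replicates = 3,
                              kinetic_params = list(
                                early = c(1, 8, 6, 3, 1.3),
                                late = c(1, 1.1, 1.3, 5, 8),
                                amp_jitter = c(0.9, 1.1),
                                gas_attenuation = 0.85),
                              basal_tags = c(30, 150),
                              chip_noise_sigma = 0.25,
                              nb_dispersion = 0.01,
                              lib_size = c(8e6, 1.2e7),
                              gc_background = 0.42,
                              promoter_prob = c(GAS = 0.20, ISRE = 0.40,
                                                BOTH = 0.45, NO_MOTIF = 0.30),
                              isg_prob = list(
                                promoter = c(GAS = 0, ISRE = 0.75, BOTH = 0.65,
                                             NO_MOTIF = 0),
                                distal = c(GAS = 0, ISRE = 0.32, BOTH = 0.27,
                                           NO_MOTIF = 0)),
                              gas_isg_prob_macrophage = c(promoter = 0.80,
                                                          distal = 0.57),
                              synergy_prob = c(BOTH_promoter = 0.60,
                                               ISRE_promoter = 0.15,
                                               other = 0.10),
                              redundant_fraction = c(promoter = 0.15,
                                                     distal = 0.45),
                              synergy_factor = 2,
                              isg_fold_range = c(8, 64),
                              codriven_fold_range = c(3, 8),
                              driver_fold_range = c(4, 16),
                              basal_rpkm = list(synergy = c(1, 4),
                                                redundant = c(8, 64),
                                                additive = c(2, 16),
                                                linked = c(4, 64),
                                                background = c(0.05, 200)),
                              gc_targets = c(synergy = 0.40, redundant = 0.60),
                              gene_length_range = c(500, 5000),
                              rna_time = 4,
                              promoter_offset = c(-800, 50),
                              distal_distance = c(1500, 4500),
                              block_span = 12000,
                              bg_gene_spacing = 700,
                              mode = c("epithelial", "macrophage"),
                              seed = 1L) {
  mode <- match.arg(mode)
  p <- as.list(environment())
  stopifnot(
    p$n_peaks > 0, p$n_background_peaks >= 0, p$peak_width >= 50,
    all(p$category_proportions >= 0), sum(p$category_proportions) > 0,
    p$n_genes > 0, p$n_isgs > 0, p$n_multipeak_genes >= 0,
    p$timepoints[1] == 0, length(p$timepoints) >= 3,
    length(p$kinetic_params$early) == length(p$timepoints),
    length(p$kinetic_params$late) == length(p$timepoints),
    p$synergy_factor > 0, p$nb_dispersion >= 0, p$chip_noise_sigma >= 0,
    p$gc_background >= 0, p$gc_background <= 1,
    p$distal_distance[2] + p$peak_width < p$block_span / 2,
    p$bg_gene_spacing > 0
  )
  p$seed <- as.integer(p$seed)
  class(p) <- "sim_params"
  p
}

# ---- truth planning --------------------------------------------------------

# Assign categories, kinetic classes, gene layout, ISG roles and expression
# parameters. Everything downstream realizes this plan.
.plan_truth <- function(p) {
  # categories: inducible then background peaks, largest-remainder each
  cat_counts <- .largest_remainder(p$n_peaks, p$category_proportions)
  cats_ind <- rep(names(cat_counts), cat_counts)
  bg_counts <- .largest_remainder(p$n_background_peaks, p$category_proportions)
  cats_bg <- rep(names(bg_counts), bg_counts)
  peaks <- data.frame(
    peak = c(sprintf("peak_%04d", seq_along(cats_ind)),
             sprintf("bgpeak_%03d", seq_along(cats_bg))),
    category = c(cats_ind, cats_bg),
    inducible_design = c(rep(TRUE, length(cats_ind)), rep(FALSE, length(cats_bg))),
    stringsAsFactors = FALSE
  )
  # kinetic class: GAS early, ISRE/BOTH late, no-motif alternating
  kin <- ifelse(peaks$category == "GAS", "early",
         ifelse(peaks$category %in% c("ISRE", "BOTH"), "late", NA))
  nm <- which(is.na(kin) & peaks$inducible_design)
  kin[nm] <- rep(c("early", "late"), length.out = length(nm))
  kin[!peaks$inducible_design] <- "flat"
  peaks$kinetic_class <- kin
  # pair up motif-categorized inducible peaks onto shared genes
  mi <- which(peaks$inducible_design & peaks$category != "NO_MOTIF")
  n_multi <- min(p$n_multipeak_genes, floor(length(mi) / 2))
  paired <- if (n_multi > 0) sample(mi, 2L * n_multi) else integer(0)
  partner <- rep(NA_integer_, nrow(peaks))
  if (n_multi > 0) {
    a <- paired[seq_len(n_multi)]
    b <- paired[n_multi + seq_len(n_multi)]
    partner[a] <- b
    partner[b] <- a
  }
  # one block (and one target gene) per peak or pair; blocks in peak order
  block_of <- rep(NA_integer_, nrow(peaks))
  nb <- 0L
  for (i in seq_len(nrow(peaks))) {
    if (!is.na(block_of[i])) next
    nb <- nb + 1L
    block_of[i] <- nb
    if (!is.na(partner[i])) block_of[partner[i]] <- nb
  }
  peaks$block <- block_of
  peaks$gene_id <- sprintf("gene_%05d", block_of)
  n_linked_genes <- nb
  if (n_linked_genes >= p$n_genes)
    stop("n_genes too small for the peak layout")
  # peak placement relative to its gene's TSS
  second <- !is.na(partner) & duplicated(block_of)
  promoter <- stats::runif(nrow(peaks)) < p$promoter_prob[peaks$category]
  promoter[second] <- FALSE  # the second peak of a pair is always distal
  offset <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (promoter[i]) {
      offset[i] <- sample(seq(p$promoter_offset[1], p$promoter_offset[2]), 1L)
    } else {
      repeat {
        d <- sample(seq(p$distal_distance[1], p$distal_distance[2]), 1L) *
          sample(c(-1L, 1L), 1L)
        j <- partner[i]
        # the two peaks of a pair must not overlap (distinct intervals and
        # unambiguous nearest-peak ordering)
        if (is.na(j) || abs(d - offset[j]) >= p$peak_width + 50L) {
          offset[i] <- d
          break
        }
      }
    }
  }
  peaks$promoter <- promoter
  peaks$tss_offset <- offset  # signed, strand-aware (downstream positive)
  truth <- list(peaks = peaks, n_linked_genes = n_linked_genes,
                cat_counts = cat_counts)
  truth
}

# decide which linked gene each pipeline-style dedup would keep, from the
# planted geometry (promoter precedence, then nearest, then peak id)
.kept_peak_per_gene <- function(peaks) {
  mp <- peaks[peaks$inducible_design & peaks$category != "NO_MOTIF", ,
              drop = FALSE]
  mp <- mp[order(mp$gene_id, !mp$promoter, abs(mp$tss_offset), mp$peak), ,
           drop = FALSE]
  mp[!duplicated(mp$gene_id), c("gene_id", "peak", "category", "promoter")]
}

.plan_expression <- function(p, truth) {
  peaks <- truth$peaks
  n_linked <- truth$n_linked_genes
  genes <- data.frame(
    gene_id = sprintf("gene_%05d", seq_len(p$n_genes)),
    linked = seq_len(p$n_genes) <= n_linked,
    stringsAsFactors = FALSE
  )
  kept <- .kept_peak_per_gene(peaks)
  m <- match(genes$gene_id, kept$gene_id)
  genes$linked_peak <- kept$peak[m]
  genes$link_category <- kept$category[m]
  genes$link_promoter <- kept$promoter[m]
  # genes whose only peaks are NO_MOTIF or background peaks count as linked
  # in the layout but carry no motif category
  no_cat <- genes$linked & is.na(genes$link_category)
  genes$link_category[no_cat] <- "NONE"
  genes$link_promoter[no_cat] <- FALSE
  # ISG membership per category x placement stratum, deterministic counts
  probs <- p$isg_prob
  if (p$mode == "macrophage") {
    probs$promoter["GAS"] <- p$gas_isg_prob_macrophage["promoter"]
    probs$distal["GAS"] <- p$gas_isg_prob_macrophage["distal"]
  }
  genes$isg <- FALSE
  for (cc in c("GAS", "ISRE", "BOTH")) {
    for (pr in c(TRUE, FALSE)) {
      idx <- which(genes$link_category %in% cc & genes$link_promoter == pr)
      prob <- if (pr) probs$promoter[cc] else probs$distal[cc]
      k <- round(length(idx) * prob)
      if (k > 0) genes$isg[sample(idx, k)] <- TRUE
    }
  }
  # top up with standalone ISGs among unlinked genes
  short <- p$n_isgs - sum(genes$isg)
  if (short > 0) {
    pool <- which(!genes$linked)
    genes$isg[sample(pool, min(short, length(pool)))] <- TRUE
  }
  # mixing-experiment role
  genes$mix_mode <- NA_character_
  isg_idx <- which(genes$isg)
  for (i in isg_idx) {
    key <- if (!is.na(genes$link_category[i]) &&
               genes$link_category[i] == "BOTH" &&
               isTRUE(genes$link_promoter[i])) "BOTH_promoter"
    else if (!is.na(genes$link_category[i]) &&
             genes$link_category[i] == "ISRE" &&
             isTRUE(genes$link_promoter[i])) "ISRE_promoter"
    else "other"
    if (stats::runif(1) < p$synergy_prob[key]) {
      genes$mix_mode[i] <- "synergy"
    } else {
      # redundant (saturating, low-ES) responses concentrate on genes
      # without promoter peaks: strongly enhanced genes need inducible
      # promoter binding, weakly enhanced ones tend to lack it
      pr_red <- if (isTRUE(genes$link_promoter[i]))
        p$redundant_fraction["promoter"] else p$redundant_fraction["distal"]
      genes$mix_mode[i] <- if (stats::runif(1) < pr_red)
        "redundant" else "additive"
    }
  }
  # expression parameters
  n <- nrow(genes)
  genes$length <- sample(seq(p$gene_length_range[1], p$gene_length_range[2]), n,
                         replace = TRUE)
  genes$basal_rpkm <- NA_real_
  genes$fold_beta_low <- 1
  genes$fold_gamma_low <- 1
  genes$fold_beta_high <- 1
  genes$synergy_factor <- NA_real_
  genes$gc_target <- p$gc_background
  bg <- !genes$linked & !genes$isg
  genes$basal_rpkm[bg] <- .logunif(sum(bg), p$basal_rpkm$background)
  ln <- genes$linked & !genes$isg
  genes$basal_rpkm[ln] <- .logunif(sum(ln), p$basal_rpkm$linked)
  for (i in isg_idx) {
    mm <- genes$mix_mode[i]
    genes$basal_rpkm[i] <- .logunif(1, p$basal_rpkm[[mm]])
    genes$fold_beta_high[i] <- .logunif(1, p$isg_fold_range)
    gas_linked <- !is.na(genes$link_category[i]) && genes$link_category[i] == "GAS"
    if (mm == "synergy") {
      genes$fold_beta_low[i] <- .logunif(1, p$codriven_fold_range)
      genes$fold_gamma_low[i] <- .logunif(1, p$codriven_fold_range)
      genes$synergy_factor[i] <- p$synergy_factor
      genes$gc_target[i] <- p$gc_targets["synergy"]
    } else if (mm == "redundant") {
      genes$fold_beta_low[i] <- .logunif(1, p$driver_fold_range)
      genes$fold_gamma_low[i] <- .logunif(1, p$driver_fold_range)
      genes$gc_target[i] <- p$gc_targets["redundant"]
    } else {  # additive: a single low-dose driver
      beta_driver <- if (gas_linked) FALSE else stats::runif(1) < 0.5
      f <- .logunif(1, p$driver_fold_range)
      if (beta_driver) genes$fold_beta_low[i] <- f
      else genes$fold_gamma_low[i] <- f
    }
    if (gas_linked) genes$fold_beta_low[i] <- 1  # dose gate on GAF targets
  }
  # expected RPKM in the mixing experiment
  b <- genes$basal_rpkm * genes$fold_beta_low
  g <- genes$basal_rpkm * genes$fold_gamma_low
  mixed <- genes$basal_rpkm
  idx <- which(genes$isg)
  for (i in idx) {
    mixed[i] <- switch(genes$mix_mode[i],
      synergy = p$synergy_factor * (b[i] + g[i]),
      additive = pmax(0, b[i] + g[i] - genes$basal_rpkm[i]),
      redundant = max(b[i], g[i]))
  }
  genes$rpkm_beta_low <- b
  genes$rpkm_gamma_low <- g
  genes$rpkm_mixed <- mixed
  genes$rpkm_beta_high <- genes$basal_rpkm * genes$fold_beta_high
  genes
}

# ---- genome ----------------------------------------------------------------

#' Simulate a genome with planted motifs and a motif-free background
#'
#' Plans the whole synthetic dataset (peak categories, kinetic classes,
#' peak-gene layout, ISG roles) and realizes a genome in which every
#' motif-category peak carries its planted GAS and/or ISRE instances while
#' the background is guaranteed motif-free by rejection resampling: any
#' window matching either motif family (on either strand) outside a
#' planted site is redrawn. Promoter GC windows of synergy and redundant
#' ISGs are stamped at their target GC.
#'
#' @param params A `"sim_params"` object.
#' @return An object of class `"sim_genome"`: `sequences` (a named
#'   `DNAStringSet`: one chromosome of linked-gene blocks, one of
#'   background genes), `tss`, `gene_lengths`, `peaks` (BED-style data
#'   frame), `truth_peaks`, `truth_genes`, `params`.
#' @export
simulate_genome <- function(params) {
  p <- params
  stopifnot(inherits(p, "sim_params"))
  set.seed(p$seed)
  truth <- .plan_truth(p)
  peaks <- truth$peaks
  genes <- .plan_expression(p, truth)
  n_linked <- truth$n_linked_genes
  # geometry: chr1 = one block per linked gene; chr2 = background genes
  S <- p$block_span
  genes$chrom <- ifelse(genes$linked, "chr1", "chr2")
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes$tss <- NA_integer_
  genes$tss[genes$linked] <- as.integer((seq_len(n_linked) - 0.5) * S)
  n_bg <- sum(!genes$linked)
  genes$tss[!genes$linked] <-
    as.integer(1000 + (seq_len(n_bg) - 0.5) * p$bg_gene_spacing)
  chr_len <- c(chr1 = n_linked * S,
               chr2 = as.integer(2000 + n_bg * p$bg_gene_spacing))
  # peak coordinates from strand-aware TSS offsets
  gm <- match(peaks$gene_id, genes$gene_id)
  sgn <- ifelse(genes$strand[gm] == "+", 1L, -1L)
  ref <- genes$tss[gm] + sgn * peaks$tss_offset
  peaks$chrom <- "chr1"
  peaks$start <- as.integer(ref - p$peak_width %/% 2)
  peaks$end <- peaks$start + as.integer(p$peak_width)
  # per-position GC probability, with stamped promoter windows
  pgc <- lapply(chr_len, function(L) rep(p$gc_background, L))
  for (i in which(genes$gc_target != p$gc_background)) {
    ch <- genes$chrom[i]
    idx <- max(1L, genes$tss[i] - 300L):min(chr_len[[ch]], genes$tss[i] + 300L)
    pgc[[ch]][idx] <- genes$gc_target[i]
  }
  chars <- lapply(names(chr_len), function(ch) {
    .scrub_sequence(.draw_bases(pgc[[ch]]), pgc[[ch]])
  })
  names(chars) <- names(chr_len)
  # plant motif instances and verify each peak's family content
  make_instance <- function(family) {
    if (family == "GAS") {
      if (stats::runif(1) < 0.1) {
        inst <- strsplit("GATTTCCCCGAATG", "")[[1]]
      } else {
        sp <- sample(2:4, 1L)
        inst <- c("T", "T", "C", sample(c("A", "C", "G", "T"), sp, replace = TRUE),
                  "G", "A", "A")
      }
    } else {
      inst <- c(strsplit("AGTTTC", "")[[1]],
                sample(c("A", "C", "G", "T"), 2L, replace = TRUE),
                "T", "T", "T", "C")
    }
    if (stats::runif(1) < 0.5) inst <- .revcomp_chars(inst)
    inst
  }
  for (i in seq_len(nrow(peaks))) {
    cc <- peaks$category[i]
    a <- peaks$start[i] + 1L  # 1-based within chrom char vector
    b <- peaks$end[i]
    want <- c(gas = cc %in% c("GAS", "BOTH"), isre = cc %in% c("ISRE", "BOTH"))
    ok <- FALSE
    for (try in 1:30) {
      seg <- chars$chr1[a:b]
      w <- length(seg)
      if (want["gas"]) {
        inst <- make_instance("GAS")
        pos <- sample(10:(w %/% 2 - length(inst)), 1L)
        seg[pos:(pos + length(inst) - 1L)] <- inst
      }
      if (want["isre"]) {
        inst <- make_instance("ISRE")
        pos <- sample((w %/% 2 + 1L):(w - 10L - length(inst)), 1L)
        seg[pos:(pos + length(inst) - 1L)] <- inst
      }
      have <- .family_present(paste(seg, collapse = ""))
      if (identical(unname(have), unname(want))) {
        chars$chr1[a:b] <- seg
        ok <- TRUE
        break
      }
      # redraw the peak interior from background and try again
      chars$chr1[a:b] <- .draw_bases(pgc$chr1[a:b])
      chars$chr1[a:b] <- .scrub_sequence(chars$chr1[a:b], pgc$chr1[a:b])
    }
    if (!ok) stop("could not plant motif content for peak ", peaks$peak[i])
  }
  sequences <- Biostrings::DNAStringSet(
    vapply(chars, paste, "", collapse = ""))
  names(sequences) <- names(chr_len)
  tss <- genes[, c("gene_id", "chrom", "tss", "strand")]
  out <- list(sequences = sequences, tss = tss,
              gene_lengths = stats::setNames(genes$length, genes$gene_id),
              peaks = peaks[, c("chrom", "start", "end", "peak")],
              truth_peaks = peaks,
              truth_genes = genes,
              params = p)
  class(out) <- "sim_genome"
  out
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("Synthetic genome: %d chromosomes (%s bp), %d peaks, %d genes\n",
              length(x$sequences),
              paste(Biostrings::width(x$sequences), collapse = " + "),
              nrow(x$peaks), nrow(x$tss)))
  cat("  planted categories: ",
      paste(names(x$truth_peaks$category |> table()),
            table(x$truth_peaks$category), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# ---- ChIP signal -----------------------------------------------------------

#' Simulate the ChIP signal matrix with planted kinetics and dose gating
#'
#' Signal is `basal x fold(t, dose) x lognormal noise` per replicate
#' column. GAS-class peaks (and early-class no-motif peaks) follow the
#' early kinetic profile and are flat below the dose gate; ISRE- and
#' BOTH-class peaks follow the late profile at both doses; background
#' peaks are flat everywhere. The planted inducible flag is true iff the
#' planted (noise-free) fold reaches the two-fold threshold in at least
#' two stimulated condition-timepoints.
#'
#' @param params A `"sim_params"` object.
#' @param genome A `"sim_genome"` from [simulate_genome()].
#' @return A list of class `"sim_signal"`: `signal` (matrix with condition
#'   column names), `peaks`, `truth_peaks` (with `inducible` and `gated`),
#'   `planted_fold` (peaks x conditions matrix of noise-free folds).
#' @export
simulate_peaks_and_signal <- function(params, genome) {
  p <- params
  stopifnot(inherits(genome, "sim_genome"))
  set.seed(p$seed + 1001L)
  tp <- peaks <- genome$truth_peaks
  stim_times <- p$timepoints[-1]
  cols <- c(sprintf("basal_0U_0h_r%d", seq_len(p$chip_replicates)))
  cond <- data.frame(column = cols, dose = 0, time = 0)
  for (d in p$doses) for (t in stim_times) {
    cn <- sprintf("beta_%gU_%gh_r%d", d, t, seq_len(p$chip_replicates))
    cols <- c(cols, cn)
    cond <- rbind(cond, data.frame(column = cn, dose = d, time = t))
  }
  n <- nrow(tp)
  basal <- .logunif(n, p$basal_tags)
  amp <- stats::runif(n, p$kinetic_params$amp_jitter[1],
                      p$kinetic_params$amp_jitter[2])
  amp[tp$category == "GAS"] <- amp[tp$category == "GAS"] *
    p$kinetic_params$gas_attenuation
  gated <- tp$category == "GAS" |
    (tp$category == "NO_MOTIF" & tp$kinetic_class == "early")
  profile_of <- function(class) switch(class,
    early = p$kinetic_params$early, late = p$kinetic_params$late,
    flat = rep(1, length(p$timepoints)))
  fold <- matrix(1, n, nrow(cond), dimnames = list(tp$peak, cond$column))
  for (i in seq_len(n)) {
    prof <- profile_of(tp$kinetic_class[i])^amp[i]
    for (j in seq_len(nrow(cond))) {
      if (cond$time[j] == 0) next
      ti <- match(cond$time[j], p$timepoints)
      f <- prof[ti]
      if (gated[i] && cond$dose[j] < p$gas_dose_gate) f <- 1
      fold[i, j] <- f
    }
  }
  noise <- if (p$chip_noise_sigma > 0)
    matrix(exp(stats::rnorm(n * nrow(cond), 0, p$chip_noise_sigma)), n)
  else matrix(1, n, nrow(cond))
  signal <- basal * fold * noise
  dimnames(signal) <- dimnames(fold)
  # planted inducible flag from the noise-free folds, averaged over
  # replicates within each stimulated condition-timepoint
  stim_keys <- unique(cond[cond$time > 0, c("dose", "time")])
  hit <- matrix(FALSE, n, nrow(stim_keys))
  for (k in seq_len(nrow(stim_keys))) {
    jj <- which(cond$dose == stim_keys$dose[k] & cond$time == stim_keys$time[k])
    hit[, k] <- rowMeans(fold[, jj, drop = FALSE]) >= 2
  }
  tp$inducible <- rowSums(hit) >= 2
  tp$gated <- gated
  out <- list(signal = signal, peaks = genome$peaks, truth_peaks = tp,
              planted_fold = fold, conditions = cond)
  class(out) <- "sim_signal"
  out
}

# ---- expression ------------------------------------------------------------

#' Simulate the RNA-seq count matrix of the mixing experiment
#'
#' Conditions: unstimulated, low-dose IFN-beta, low-dose IFN-gamma, the
#' mixture of the two low doses, and high-dose IFN-beta, each with
#' `rna_replicates` replicates at `rna_time` hours. Counts are
#' negative-binomial around the planted expected CPM (`nb_dispersion = 0`
#' gives deterministic rounded means). Synergy genes reach
#' `synergy_factor` times the summed single-stimulus RPKM in the mixed
#' condition; in epithelial mode genes linked to GAS-only peaks stay at
#' fold 1 in every condition.
#'
#' @param params A `"sim_params"` object.
#' @param genome A `"sim_genome"` from [simulate_genome()].
#' @return A list of class `"sim_expression"`: `counts`, `gene_lengths`,
#'   `truth_genes`, `expected_rpkm` (genes x conditions), `lib_sizes`.
#' @export
simulate_expression <- function(params, genome) {
  p <- params
  stopifnot(inherits(genome, "sim_genome"))
  set.seed(p$seed + 2002L)
  g <- genome$truth_genes
  conds <- list(
    basal = sprintf("basal_0U_0h_r%d", seq_len(p$rna_replicates)),
    beta_low = sprintf("beta_1U_%gh_r%d", p$rna_time, seq_len(p$rna_replicates)),
    gamma_low = sprintf("gamma_1ng_%gh_r%d", p$rna_time, seq_len(p$rna_replicates)),
    mixed = sprintf("mixed_1U_%gh_r%d", p$rna_time, seq_len(p$rna_replicates)),
    beta_high = sprintf("beta_10U_%gh_r%d", p$rna_time, seq_len(p$rna_replicates))
  )
  rpkm_exp <- cbind(basal = g$basal_rpkm, beta_low = g$rpkm_beta_low,
                    gamma_low = g$rpkm_gamma_low, mixed = g$rpkm_mixed,
                    beta_high = g$rpkm_beta_high)
  rownames(rpkm_exp) <- g$gene_id
  cpm_exp <- rpkm_exp * (g$length / 1e3)
  cols <- unlist(conds, use.names = FALSE)
  lib <- .logunif(length(cols), p$lib_size)
  names(lib) <- cols
  counts <- matrix(0, nrow(g), length(cols),
                   dimnames = list(g$gene_id, cols))
  for (j in seq_along(cols)) {
    cond <- rep(names(conds), lengths(conds))[j]
    mu <- cpm_exp[, cond] * lib[j] / 1e6
    counts[, j] <- if (p$nb_dispersion > 0)
      stats::rnbinom(nrow(g), mu = mu, size = 1 / p$nb_dispersion)
    else round(mu)
  }
  out <- list(counts = counts,
              gene_lengths = genome$gene_lengths,
              truth_genes = g,
              expected_rpkm = rpkm_exp,
              lib_sizes = lib,
              condition_columns = conds)
  class(out) <- "sim_expression"
  out
}

# ---- full dataset ----------------------------------------------------------

#' Simulate the full coupled dataset
#'
#' Runs [simulate_genome()], [simulate_peaks_and_signal()] and
#' [simulate_expression()] and optionally writes every artifact to `dir`
#' as plain text: `genome.fa`, `peaks.bed`, `chip_signal.tsv`,
#' `counts.tsv`, `gene_lengths.tsv`, `tss.tsv`, `truth_peaks.tsv`,
#' `truth_genes.tsv`.
#'
#' @param params A `"sim_params"` object.
#' @param dir Output directory (created if missing), or NULL to keep
#'   everything in memory.
#' @return A list of class `"ifn_simulation"` with `genome`, `chip`,
#'   `rna`, `params` and (when written) `files`.
#' @export
simulate_dataset <- function(params = simulation_params(), dir = NULL) {
  genome <- simulate_genome(params)
  chip <- simulate_peaks_and_signal(params, genome)
  rna <- simulate_expression(params, genome)
  out <- list(genome = genome, chip = chip, rna = rna, params = params)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(genome$sequences, fa)
    write_bed(genome$peaks, file.path(dir, "peaks.bed"))
    write_matrix(chip$signal, file.path(dir, "chip_signal.tsv"), "peak")
    write_matrix(rna$counts, file.path(dir, "counts.tsv"), "gene_id")
    utils::write.table(
      data.frame(gene_id = names(rna$gene_lengths), length = rna$gene_lengths),
      file.path(dir, "gene_lengths.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(genome$tss, file.path(dir, "tss.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(chip$truth_peaks, file.path(dir, "truth_peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rna$truth_genes, file.path(dir, "truth_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$files <- list.files(dir, full.names = TRUE)
  }
  class(out) <- "ifn_simulation"
  out
}

#' @export
print.ifn_simulation <- function(x, ...) {
  cat("Synthetic interferon dataset\n")
  cat(sprintf("  peaks: %d (%d inducible), genes: %d (%d ISGs), mode: %s\n",
              nrow(x$chip$truth_peaks), sum(x$chip$truth_peaks$inducible),
              nrow(x$rna$truth_genes), sum(x$rna$truth_genes$isg),
              x$params$mode))
  invisible(x)
}
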