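# IUPAC nucleotide codes -> regex character classes. N deliberately maps to
# [ACGT]: an N in the *subject* sequence never satisfies a motif position.
.iupac_class <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

.iupac_regex <- function(block) {
  chars <- strsplit(block, "")[[1]]
  bad <- setdiff(chars, names(.iupac_class))
  if (length(bad)) stop("invalid IUPAC letters in motif: ", paste(bad, collapse = ""))
  paste(.iupac_class[chars], collapse = "")
}

#' Compile a consensus motif with variable-length spacers
#'
#' Motif patterns are IUPAC strings with `N{min,max}` (or `N{n}`) spacer
#' syntax between fixed blocks, e.g. the GAS consensus `"TTCN{2,4}GAA"` or
#' the ISRE consensus `"AGTTTCN{2}TTTC"`. A plain `N` inside a block is an
#' ambiguous position matching any single base.
#'
#' @param pattern Pattern string.
#' @param family `"GAS_family"` or `"ISRE_family"`.
#' @param name Motif label (defaults to the pattern).
#' @return An object of class `"motif_model"` with fields `name`, `family`,
#'   `blocks`, `spacer_min`, `spacer_max`, `min_length`, `max_length`,
#'   `mode = "consensus"`.
#' @examples
#' compile_motif("TTCN{2,4}GAA", "GAS_family")
#' @export
compile_motif <- function(pattern, family = c("GAS_family", "ISRE_family"),
                          name = pattern) {
  family <- match.arg(family)
  if (!nzchar(pattern)) stop("empty motif pattern")
  spacer_pat <- "N\\{([0-9]+)(,([0-9]+))?\\}"
  m <- gregexpr(spacer_pat, pattern)[[1]]
  if (m[1] == -1L) {
    blocks <- pattern
    smin <- integer(0); smax <- integer(0)
  } else {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    caps <- regmatches(pattern, gregexpr(spacer_pat, pattern))[[1]]
    smin <- as.integer(sub(spacer_pat, "\\1", caps))
    smax <- ifelse(sub(spacer_pat, "\\3", caps) == "", smin,
                   as.integer(sub(spacer_pat, "\\3", caps)))
    smax <- as.integer(smax)
    # blocks are the stretches between (and around) the spacers
    cut_from <- c(1L, starts + lens)
    cut_to <- c(starts - 1L, nchar(pattern))
    blocks <- substring(pattern, cut_from, cut_to)
    if (any(!nzchar(blocks)))
      stop("motif pattern must start and end with a fixed block, ",
           "with exactly one spacer between consecutive blocks")
  }
  if (any(smin > smax)) stop("spacer min > max in motif pattern: ", pattern)
  for (b in blocks) .iupac_regex(b)  # validates letters
  model <- list(
    name = name, family = family, mode = "consensus",
    blocks = blocks, spacer_min = smin, spacer_max = smax,
    min_length = sum(nchar(blocks)) + sum(smin),
    max_length = sum(nchar(blocks)) + sum(smax)
  )
  class(model) <- "motif_model"
  model
}

#' Build a position-weight-matrix motif
#'
#' Alternative scanning mode for user-supplied matrices. A window matches
#' when its log2 odds score against a uniform background reaches
#' `threshold`. Windows containing N never match.
#'
#' @param pwm Numeric matrix, rows named A, C, G, T, columns summing to 1.
#' @param family Motif family for categorization.
#' @param threshold Log2-odds score threshold.
#' @param name Motif label.
#' @param pseudo Probability pseudocount applied before taking logs.
#' @return A `"motif_model"` with `mode = "pwm"`.
#' @export
pwm_motif <- function(pwm, family = c("GAS_family", "ISRE_family"),
                      threshold, name = "pwm", pseudo = 1e-3) {
  family <- match.arg(family)
  pwm <- as.matrix(pwm)
  if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
  pwm <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(abs(colSums(pwm) - 1) > 1e-6)) stop("pwm columns must sum to 1")
  score <- log2((pwm + pseudo) / (0.25 + pseudo))
  model <- list(name = name, family = family, mode = "pwm",
                score = score, threshold = threshold,
                min_length = ncol(pwm), max_length = ncol(pwm))
  class(model) <- "motif_model"
  model
}

#' @export
print.motif_model <- function(x, ...) {
  if (x$mode == "consensus") {
    gaps <- if (length(x$spacer_min))
      paste(sprintf("N{%d,%d}", x$spacer_min, x$spacer_max), collapse = "")
    else ""
    cat(sprintf("motif %s (%s): %s  [length %d-%d]\n", x$name, x$family,
                paste(x$blocks, collapse = gaps), x$min_length, x$max_length))
  } else {
    cat(sprintf("PWM motif %s (%s): width %d, log2-odds threshold %.2f\n",
                x$name, x$family, x$max_length, x$threshold))
  }
  invisible(x)
}

#' The consensus motif set used for peak categorization
#'
#' Three consensus models: the canonical GAS element `TTCN{2,4}GAA`, the
#' variant GAS element found in the Irf1 promoter (`GATTTCCCCGAATG`), and
#' the ISRE element `AGTTTCN{2}TTTC`.
#'
#' @return A named list of `"motif_model"` objects.
#' @export
default_motifs <- function() {
  list(
    GAS = compile_motif("TTCN{2,4}GAA", "GAS_family", name = "GAS"),
    GAS_variant = compile_motif("GATTTCCCCGAATG", "GAS_family", name = "GAS_variant"),
    ISRE = compile_motif("AGTTTCN{2}TTTC", "ISRE_family", name = "ISRE")
  )
}

.revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

# all (possibly overlapping) start offsets of a fixed-length regex
.overlap_starts <- function(seq, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

.scan_consensus_one_strand <- function(seq, motif) {
  out <- list()
  gaps <- length(motif$spacer_min)
  combos <- if (gaps == 0L) {
    matrix(integer(0), nrow = 1L, ncol = 0L)
  } else {
    as.matrix(expand.grid(lapply(seq_len(gaps), function(i)
      motif$spacer_min[i]:motif$spacer_max[i])))
  }
  block_re <- vapply(motif$blocks, .iupac_regex, "")
  for (r in seq_len(nrow(combos))) {
    sp <- combos[r, ]
    parts <- character(0)
    for (i in seq_along(motif$blocks)) {
      parts <- c(parts, block_re[i])
      if (i <= length(sp)) parts <- c(parts, sprintf("[ACGT]{%d}", sp[i]))
    }
    len <- sum(nchar(motif$blocks)) + sum(sp)
    offs <- .overlap_starts(seq, paste(parts, collapse = ""))
    if (length(offs)) {
      out[[length(out) + 1L]] <- data.frame(
        offset = offs, length = len,
        spacer = if (length(sp)) unname(sp[1]) else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(offset = integer(0), length = integer(0), spacer = integer(0))
}

.scan_pwm_one_strand <- function(seq, motif) {
  w <- motif$max_length
  n <- nchar(seq)
  if (n < w) return(data.frame(offset = integer(0), length = integer(0),
                               spacer = integer(0)))
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))  # NA for N and friends
  sc <- motif$score
  offs <- integer(0)
  for (off in 0:(n - w)) {
    win <- idx[(off + 1):(off + w)]
    if (anyNA(win)) next
    s <- sum(sc[cbind(win, seq_len(w))])
    if (s >= motif$threshold) offs <- c(offs, off)
  }
  data.frame(offset = offs, length = rep.int(w, length(offs)),
             spacer = rep(NA_integer_, length(offs)))
}

#' Scan a sequence for motif matches on one or both strands
#'
#' Reports every match, including overlapping matches and all admissible
#' spacer lengths at the same position. Reverse-strand matches are scanned
#' on the reverse complement and reported in forward coordinates (offset of
#' the match's leftmost base on the forward sequence). Matches are ordered
#' by position, then strand (`+` first), then shorter spacer. `N` in the
#' subject sequence matches nothing.
#'
#' @param seq Nucleotide string over A/C/G/T/N.
#' @param motif A `"motif_model"`.
#' @param both_strands Scan the reverse complement as well?
#' @return A data frame with columns `motif`, `offset`, `strand`, `length`,
#'   `spacer`.
#' @examples
#' gas <- compile_motif("TTCN{2,4}GAA", "GAS_family")
#' scan_motif("TACAACAGCCTGATTTCCCCGAAATGACGC", gas)
#' @export
scan_motif <- function(seq, motif, both_strands = TRUE) {
  stopifnot(inherits(motif, "motif_model"))
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence must be over A/C/G/T/N")
  scan1 <- if (motif$mode == "consensus") .scan_consensus_one_strand else .scan_pwm_one_strand
  fwd <- scan1(seq, motif)
  fwd$strand <- rep("+", nrow(fwd))
  hits <- fwd
  if (both_strands) {
    rc <- scan1(.revcomp(seq), motif)
    rc$strand <- rep("-", nrow(rc))
    if (nrow(rc)) rc$offset <- nchar(seq) - (rc$offset + rc$length)
    hits <- rbind(fwd, rc)
  }
  hits <- hits[order(hits$offset, hits$strand, hits$length), , drop = FALSE]
  rownames(hits) <- NULL
  data.frame(motif = rep(motif$name, nrow(hits)), hits,
             stringsAsFactors = FALSE)
}

#' Categorize peaks by motif-family hit counts
#'
#' A peak with at least one GAS-family match and no ISRE-family match is a
#' `GAS` peak; the reverse is an `ISRE` peak; at least one of each makes a
#' `BOTH` peak; neither makes a `NO_MOTIF` peak.
#'
#' @param gas_hits,isre_hits Non-negative integer vectors of match counts.
#' @return Character vector over `GAS`, `ISRE`, `BOTH`, `NO_MOTIF`.
#' @examples
#' categorize_peak(c(3, 0, 1, 0), c(0, 2, 1, 0))
#' @export
categorize_peak <- function(gas_hits, isre_hits) {
  if (length(gas_hits) != length(isre_hits))
    stop("gas_hits and isre_hits must have equal length")
  if (any(gas_hits < 0) || any(isre_hits < 0)) stop("hit counts must be >= 0")
  ifelse(gas_hits > 0 & isre_hits == 0, "GAS",
  ifelse(gas_hits == 0 & isre_hits > 0, "ISRE",
  ifelse(gas_hits > 0 & isre_hits > 0, "BOTH", "NO_MOTIF")))
}

#' Scan and categorize peaks against a genome
#'
#' Extracts each peak's sequence, scans it with every motif in `motifs` on
#' both strands, and assigns the GAS/ISRE/BOTH/NO_MOTIF category from the
#' family-level presence calls.
#'
#' @param peaks Data frame with `chrom`, `start`, `end`, `peak` (0-based
#'   half-open).
#' @param genome Named `DNAStringSet` or named character vector.
#' @param motifs List of `"motif_model"` objects (default [default_motifs()]).
#' @return A data frame with `peak`, `gas_hits`, `isre_hits`, `category`.
#' @export
classify_peaks <- function(peaks, genome, motifs = default_motifs()) {
  stopifnot(all(c("chrom", "start", "end", "peak") %in% names(peaks)))
  fams <- vapply(motifs, `[[`, "", "family")
  gas <- integer(nrow(peaks)); isre <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    seq <- get_sequence(genome, peaks$chrom[i], peaks$start[i], peaks$end[i])
    nhit <- vapply(motifs, function(mo) nrow(scan_motif(seq, mo)), 0L)
    gas[i] <- sum(nhit[fams == "GAS_family"])
    isre[i] <- sum(nhit[fams == "ISRE_family"])
  }
  data.frame(peak = peaks$peak, gas_hits = gas, isre_hits = isre,
             category = categorize_peak(gas, isre),
             stringsAsFactors = FALSE)
}

#' Categorize genomic locations by cross-genotype TF presence
#'
#' Macrophage-mode categorization from peak presence across datasets:
#' locations with a STAT1 peak but no IRF9 peak in wild-type cells are GAF
#' binding events; locations with an IRF9 peak in wild-type cells and no
#' STAT1 or STAT2 peak in Irf9-null cells are ISGF3 binding events; all
#' other combinations are OTHER.
#'
#' @param stat1_wt,irf9_wt Logical: peak present in wild-type STAT1 / IRF9
#'   ChIP-seq.
#' @param stat1_ko,stat2_ko Logical: peak present in Irf9-null STAT1 /
#'   STAT2 ChIP-seq.
#' @return Character vector over `GAF`, `ISGF3`, `OTHER`.
#' @examples
#' categorize_by_tf_presence(TRUE, FALSE, FALSE, FALSE)
#' @export
categorize_by_tf_presence <- function(stat1_wt, irf9_wt, stat1_ko, stat2_ko) {
  n <- max(length(stat1_wt), length(irf9_wt), length(stat1_ko), length(stat2_ko))
  stat1_wt <- rep_len(as.logical(stat1_wt), n)
  irf9_wt <- rep_len(as.logical(irf9_wt), n)
  stat1_ko <- rep_len(as.logical(stat1_ko), n)
  stat2_ko <- rep_len(as.logical(stat2_ko), n)
  ifelse(stat1_wt & !irf9_wt, "GAF",
  ifelse(irf9_wt & !stat1_ko & !stat2_ko, "ISGF3", "OTHER"))
}
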