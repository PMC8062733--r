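#' Read peak intervals from a BED file
#'
#' Minimal BED4 reader. Coordinates are kept in the BED convention: 0-based,
#' half-open \[start, end). The fourth column, when present, is kept as the
#' peak identifier; otherwise identifiers `peak_1 ... peak_n` are assigned in
#' file order. Extra columns are ignored.
#'
#' @param path Path to a tab-separated BED file with at least 3 columns.
#' @return A data frame with columns `chrom`, `start`, `end`, `peak`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t300\tpk1", f)
#' read_bed(f)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), peak = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  if (any(chrom == "")) stop("malformed BED line ", which(chrom == "")[1], ": empty chrom")
  if (any(start < 0)) stop("invalid BED line ", which(start < 0)[1], ": start < 0")
  if (any(end <= start)) stop("invalid BED line ", which(end <= start)[1], ": end <= start")
  peak <- ifelse(nf >= 4L, vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "", ""),
                 paste0("peak_", seq_along(fields)))
  data.frame(chrom = chrom, start = start, end = end, peak = peak,
             stringsAsFactors = FALSE)
}

#' Write peak intervals to a BED file
#'
#' Inverse of [read_bed()]: writes `chrom`, `start`, `end`, `peak` as BED4,
#' preserving the 0-based half-open convention.
#'
#' @param peaks Data frame with columns `chrom`, `start`, `end` and
#'   optionally `peak`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  peak <- if ("peak" %in% names(peaks)) peaks$peak else paste0("peak_", seq_len(nrow(peaks)))
  out <- paste(peaks$chrom, format(peaks$start, scientific = FALSE, trim = TRUE),
               format(peaks$end, scientific = FALSE, trim = TRUE), peak, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Load a genome from a FASTA file
#'
#' @param path Path to an (optionally gzipped) FASTA file.
#' @return A named [Biostrings::DNAStringSet] keyed by chromosome name
#'   (first whitespace-separated token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Extract a genomic subsequence
#'
#' Strand-aware lookup on 0-based half-open coordinates. Minus-strand
#' requests return the reverse complement. Output is always upper case.
#'
#' @param genome A named `DNAStringSet` (or named character vector of
#'   sequences).
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"`, `"-"` or `"."` (treated as `"+"`).
#' @return A single character string.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chrT = "AAAC"))
#' get_sequence(g, "chrT", 1, 4, "-")  # "GTT"
#' @export
get_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || end <= start)
    stop(sprintf("range [%d, %d) out of bounds for %s (length %d)",
                 start, end, chrom, len))
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (identical(strand, "-")) s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

#' Parse condition metadata from matrix column names
#'
#' Columns of signal and expression matrices follow the convention
#' `stimulus_<dose><unit>_<time>h_r<replicate>`, e.g. `beta_10U_2h_r1` or
#' `gamma_1ng_4h_r2`. Names that do not parse are kept but flagged, and are
#' excluded from operations that need metadata.
#'
#' @param columns Character vector of column names.
#' @return A data frame with `column`, `stimulus`, `dose`, `unit`, `time`,
#'   `replicate`, `parsed`.
#' @examples
#' parse_conditions(c("beta_10U_2h_r1", "whatever"))
#' @export
parse_conditions <- function(columns) {
  pat <- "^([A-Za-z][A-Za-z0-9]*)_([0-9.]+)([A-Za-z]*)_([0-9.]+)h_r([0-9]+)$"
  m <- regmatches(columns, regexec(pat, columns))
  parsed <- lengths(m) == 6L
  take <- function(i, cast = identity) {
    vapply(seq_along(m), function(j) {
      if (parsed[j]) cast(m[[j]][i]) else cast(NA_character_)
    }, cast("1"))
  }
  data.frame(
    column = columns,
    stimulus = take(2L),
    dose = take(3L, as.numeric),
    unit = take(4L),
    time = take(5L, as.numeric),
    replicate = take(6L, function(x) as.integer(as.numeric(x))),
    parsed = parsed,
    stringsAsFactors = FALSE
  )
}

#' Read a numeric matrix with row identifiers from TSV
#'
#' First column holds row identifiers (peaks or genes); remaining columns
#' are numeric. Column condition metadata is parsed from the column names
#' (see [parse_conditions()]) and attached as the `"conditions"` attribute.
#'
#' @param path Path to a rectangular TSV with a header row.
#' @return A numeric matrix with rownames, with attribute `conditions`.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix must have a row-id column plus data columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))], collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in matrix ", path)
  rownames(m) <- ids
  attr(m, "conditions") <- parse_conditions(colnames(m))
  m
}

#' Write a numeric matrix with row identifiers to TSV
#'
#' Round-trips with [read_matrix()]: decimal representations written here
#' are re-read bit-exactly.
#'
#' @param m Numeric matrix with rownames.
#' @param path Output path.
#' @param id_name Header for the row-id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_name = "id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' The annotation interchange format is a 4-column TSV: `gene_id`, `chrom`,
#' `tss` (0-based base position of the transcription start site) and
#' `strand` (`+`/`-`).
#'
#' @param path Path to the TSV (with header).
#' @return A data frame with one row per gene.
#' @export
read_tss <- function(path) {
  if (!file.exists(path)) stop("TSS file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(df))) {
    stop("TSS table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in TSS table")
  if (!all(df$strand %in% c("+", "-"))) stop("TSS strand must be '+' or '-'")
  df[need]
}

#' Extract per-gene TSS positions from a GTF file
#'
#' Helper mapping transcript records to a single strand-aware TSS per gene:
#' the transcript start (plus strand) or end (minus strand) of the first
#' transcript per gene, with a lexicographic tie-break on transcript
#' identifier. Positions are converted to the package's 0-based convention.
#'
#' @param path Path to a GTF file.
#' @return A TSS annotation data frame as in [read_tss()].
#' @export
import_gtf_tss <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  tx <- gr[gr$type == "transcript"]
  if (length(tx) == 0L) tx <- gr  # fall back to any feature rows
  md <- S4Vectors::mcols(tx)
  gene <- as.character(md$gene_id)
  txid <- if ("transcript_id" %in% names(md)) as.character(md$transcript_id) else gene
  ord <- order(gene, txid)
  tx <- tx[ord]; gene <- gene[ord]
  keep <- !duplicated(gene)
  tx <- tx[keep]; gene <- gene[keep]
  strand <- as.character(BiocGenerics::strand(tx))
  strand[strand == "*"] <- "+"
  tss1 <- ifelse(strand == "+", BiocGenerics::start(tx), BiocGenerics::end(tx))
  data.frame(gene_id = gene,
             chrom = as.character(GenomicRanges::seqnames(tx)),
             tss = as.integer(tss1) - 1L,  # 1-based GRanges -> 0-based
             strand = strand,
             stringsAsFactors = FALSE)
}
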