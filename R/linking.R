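#' Reference point of a peak
#'
#' The summit when one is provided, otherwise the floor of the interval
#' midpoint.
#'
#' @param peaks Data frame with `start`, `end` and optionally `summit`
#'   (absolute position).
#' @return Integer vector of reference positions.
#' @examples
#' peak_reference_point(data.frame(start = 100, end = 301))  # 200
#' @export
peak_reference_point <- function(peaks) {
  mid <- as.integer(floor((peaks$start + peaks$end) / 2))
  if ("summit" %in% names(peaks)) {
    s <- peaks$summit
    mid <- ifelse(!is.na(s), as.integer(s), mid)
  }
  mid
}

#' Link peaks to their closest expressed genes
#'
#' Each peak is linked to the nearest expressed gene on its chromosome by
#' distance between the peak reference point and the gene TSS. Ties are
#' broken by the smaller signed-distance magnitude, then lexicographically
#' by gene identifier. The signed distance is strand-aware (positive =
#' downstream of the TSS in the gene's orientation) and the promoter flag
#' is true when it falls inside `promoter_window` (bounds inclusive). Peaks
#' on chromosomes without any expressed gene are flagged `unassigned`.
#'
#' @param peaks Data frame with `chrom`, `start`, `end`, `peak`, optionally
#'   `summit` and `category`.
#' @param tss TSS annotation data frame (`gene_id`, `chrom`, `tss`,
#'   `strand`), e.g. from [read_tss()].
#' @param expressed Character vector of expressed gene identifiers, or NULL
#'   for all annotated genes.
#' @param promoter_window Signed window around the TSS, default
#'   `c(-1000, 100)`.
#' @return A data frame of links: `peak`, `gene_id`, `signed_distance`,
#'   `distance`, `promoter`, `category`, `unassigned`.
#' @export
link_peaks <- function(peaks, tss, expressed = NULL,
                       promoter_window = c(-1000, 100)) {
  stopifnot(all(c("chrom", "start", "end", "peak") %in% names(peaks)),
            all(c("gene_id", "chrom", "tss", "strand") %in% names(tss)))
  if (!is.null(expressed)) tss <- tss[tss$gene_id %in% expressed, , drop = FALSE]
  ref <- peak_reference_point(peaks)
  n <- nrow(peaks)
  gene <- rep(NA_character_, n); sdist <- rep(NA_real_, n)
  for (ch in unique(peaks$chrom)) {
    g <- tss[tss$chrom == ch, , drop = FALSE]
    pi <- which(peaks$chrom == ch)
    if (nrow(g) == 0L) next
    g <- g[order(g$gene_id), , drop = FALSE]  # lexicographic tie-break base
    for (i in pi) {
      d_abs <- abs(ref[i] - g$tss)
      j <- which(d_abs == min(d_abs))
      if (length(j) > 1L) j <- j[1L]  # equal |d|: first in gene_id order
      gene[i] <- g$gene_id[j]
      sdist[i] <- ifelse(g$strand[j] == "+", ref[i] - g$tss[j], g$tss[j] - ref[i])
    }
  }
  promoter <- !is.na(sdist) & sdist >= promoter_window[1] & sdist <= promoter_window[2]
  data.frame(
    peak = peaks$peak,
    gene_id = gene,
    signed_distance = sdist,
    distance = abs(sdist),
    promoter = promoter,
    category = if ("category" %in% names(peaks)) peaks$category else NA_character_,
    unassigned = is.na(gene),
    stringsAsFactors = FALSE
  )
}

#' Collapse peak links to one link per gene
#'
#' When several peaks link to one gene, the promoter link is kept if any
#' exists (the nearest among promoter links); otherwise the nearest link.
#' Remaining ties break lexicographically on peak identifier. The kept
#' link's motif category labels the gene.
#'
#' @param links Link data frame from [link_peaks()] (unassigned links are
#'   dropped).
#' @return A data frame with one row per gene: `gene_id`, `peak`,
#'   `signed_distance`, `distance`, `promoter`, `category`, `n_peaks`.
#' @export
unique_gene_table <- function(links) {
  links <- links[!links$unassigned, , drop = FALSE]
  if (nrow(links) == 0L) return(links)
  links <- links[order(links$gene_id, !links$promoter, links$distance, links$peak), ,
                 drop = FALSE]
  npk <- table(links$gene_id)
  keep <- links[!duplicated(links$gene_id), , drop = FALSE]
  keep$n_peaks <- as.integer(npk[keep$gene_id])
  keep$unassigned <- NULL
  rownames(keep) <- NULL
  keep[order(keep$gene_id), , drop = FALSE]
}

#' Per-category distances from peaks to their nearest TSS
#'
#' @param links Link data frame from [link_peaks()].
#' @return A list with `distances` (named list of numeric vectors by
#'   category) and `medians` (named numeric vector).
#' @export
distance_distribution <- function(links) {
  links <- links[!links$unassigned, , drop = FALSE]
  cat <- if (all(is.na(links$category))) rep("ALL", nrow(links)) else links$category
  dists <- split(links$distance, cat)
  list(distances = dists, medians = vapply(dists, stats::median, 0))
}

#' Summary counts of linked genes by category and promoter status
#'
#' @param gene_table One-link-per-gene table from [unique_gene_table()].
#' @return A data frame with `category`, `promoter`, `distal`, `total`.
#' @export
link_summary <- function(gene_table) {
  cats <- sort(unique(gene_table$category))
  out <- do.call(rbind, lapply(cats, function(cc) {
    g <- gene_table[gene_table$category == cc, , drop = FALSE]
    data.frame(category = cc, promoter = sum(g$promoter),
               distal = sum(!g$promoter), total = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rbind(out, data.frame(category = "ALL", promoter = sum(gene_table$promoter),
                        distal = sum(!gene_table$promoter),
                        total = nrow(gene_table), stringsAsFactors = FALSE))
}
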