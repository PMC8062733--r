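#' Analysis configuration
#'
#' Collects every threshold the pipeline uses, with the defaults applied
#' throughout the analysis: two-fold induction over basal in at least two
#' timepoints for inducible peaks; ISG calling at FDR < 0.05 and
#' fold-change > 2; a 2-CPM expression floor; the promoter window -1000 to
#' +100 bp around the TSS; the GC window -300 to +300 bp around the TSS; a
#' 1-RPKM pseudocount for expression ratios and a 1-tag pseudocount for
#' ChIP signal ratios; and k = 2 candidate kinetic clusters selected by
#' silhouette.
#'
#' @param induction_fold Fold threshold over basal for an inducible peak.
#' @param min_timepoints Minimum number of stimulated timepoints at or above
#'   `induction_fold`.
#' @param isg_fdr BH-adjusted FDR threshold for ISG membership.
#' @param isg_fold Fold-change threshold (with pseudocount) for ISG
#'   membership and induced-fraction counts.
#' @param cpm_filter Genes below this CPM in all samples are dropped.
#' @param promoter_window Length-2 signed window (bp relative to TSS,
#'   strand-aware, inclusive) defining a promoter peak.
#' @param gc_window Length-2 signed window around the TSS for promoter GC
#'   content.
#' @param rpkm_pseudocount Pseudocount (RPKM) for fold-change and
#'   Enhancement-score ratios.
#' @param signal_pseudocount Pseudocount (normalized tags) for ChIP signal
#'   ratios and log2 transforms.
#' @param kmeans_k Candidate numbers of kinetic clusters (selection by mean
#'   silhouette width).
#' @param exclude_columns Signal-matrix columns excluded from the inducible
#'   test (outlier replicates); they remain available elsewhere.
#' @param seed Integer seed controlling every stochastic step.
#' @return A list of class `"ifn_config"`.
#' @examples
#' cfg <- analysis_config()
#' cfg$promoter_window
#' @export
analysis_config <- function(induction_fold = 2,
                            min_timepoints = 2,
                            isg_fdr = 0.05,
                            isg_fold = 2,
                            cpm_filter = 2,
                            promoter_window = c(-1000, 100),
                            gc_window = c(-300, 300),
                            rpkm_pseudocount = 1,
                            signal_pseudocount = 1,
                            kmeans_k = 2:6,
                            exclude_columns = character(),
                            seed = 1L) {
  cfg <- list(
    induction_fold = induction_fold, min_timepoints = min_timepoints,
    isg_fdr = isg_fdr, isg_fold = isg_fold, cpm_filter = cpm_filter,
    promoter_window = as.numeric(promoter_window),
    gc_window = as.numeric(gc_window),
    rpkm_pseudocount = rpkm_pseudocount,
    signal_pseudocount = signal_pseudocount,
    kmeans_k = as.integer(kmeans_k),
    exclude_columns = as.character(exclude_columns),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$induction_fold > 0, cfg$min_timepoints > 0, cfg$isg_fdr > 0,
    cfg$isg_fold > 0, cfg$cpm_filter >= 0,
    length(cfg$promoter_window) == 2, cfg$promoter_window[1] < cfg$promoter_window[2],
    length(cfg$gc_window) == 2, cfg$gc_window[1] < cfg$gc_window[2],
    cfg$rpkm_pseudocount > 0, cfg$signal_pseudocount > 0,
    all(cfg$kmeans_k >= 2)
  )
  class(cfg) <- "ifn_config"
  cfg
}

#' Read an analysis configuration from a YAML file
#'
#' Every key is optional; missing keys take the [analysis_config()] defaults.
#' Unknown keys are rejected so typos do not silently revert to defaults.
#'
#' @param path Path to a YAML file.
#' @return An `"ifn_config"` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @export
print.ifn_config <- function(x, ...) {
  cat("Analysis configuration\n")
  for (k in names(x)) {
    cat(sprintf("  %-18s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}
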