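#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end on a dataset: classify peaks by motif
#' content, find inducible peaks from the signal time course, cluster their
#' kinetics, test dose sensitivity of the GAS and ISRE subsets, normalize
#' expression and call ISGs, link motif-categorized inducible peaks to
#' their closest expressed genes, compute induced fractions per category,
#' and assemble Enhancement records with quartile comparisons.
#'
#' @param data Either an `"ifn_simulation"` (from [simulate_dataset()]) or
#'   a list with elements `genome` (named sequences), `peaks` (BED data
#'   frame), `signal` (matrix), `counts` (matrix), `gene_lengths` (named
#'   vector), `tss` (data frame).
#' @param config An `"ifn_config"` from [analysis_config()].
#' @param outdir Optional directory; when given, stage outputs and the run
#'   manifest are written as TSV.
#' @return An object of class `"ifn_run"` with elements `classification`,
#'   `inducible`, `clusters`, `dose`, `norm`, `expressed`, `isgs`, `links`,
#'   `gene_table`, `link_counts`, `induced_by_category`, `records`,
#'   `quartiles`, `comparison`, `es_by_motif`, `manifest`.
#' @export
run_ifn_pipeline <- function(data, config = analysis_config(), outdir = NULL) {
  if (inherits(data, "ifn_simulation")) {
    inputs <- list(genome = data$genome$sequences,
                   peaks = data$genome$peaks,
                   signal = data$chip$signal,
                   counts = data$rna$counts,
                   gene_lengths = data$genome$gene_lengths,
                   tss = data$genome$tss)
  } else inputs <- data
  need <- c("genome", "peaks", "signal", "counts", "gene_lengths", "tss")
  missing <- setdiff(need, names(inputs))
  if (length(missing)) stop("pipeline inputs missing: ", paste(missing, collapse = ", "))

  # stage 1: inducible peaks from the signal time course
  inducible <- find_inducible(inputs$signal,
                              fold = config$induction_fold,
                              min_timepoints = config$min_timepoints,
                              pseudocount = config$signal_pseudocount,
                              exclude_cols = config$exclude_columns)

  # stage 2: motif categorization of the inducible peaks
  ipeaks <- inputs$peaks[inputs$peaks$peak %in% names(inducible)[inducible], ,
                         drop = FALSE]
  classification <- classify_peaks(ipeaks, inputs$genome)
  ipeaks$category <- classification$category[match(ipeaks$peak, classification$peak)]

  # stage 3: kinetic clustering of inducible peaks (high-dose time course)
  meta <- parse_conditions(colnames(inputs$signal))
  high_dose <- max(meta$dose[meta$parsed & meta$time > 0])
  kin_cols <- meta$column[meta$parsed & (meta$time == 0 | meta$dose == high_dose)]
  kin_meta <- meta[match(kin_cols, meta$column), , drop = FALSE]
  avg <- .average_replicates(inputs$signal[ipeaks$peak, kin_cols, drop = FALSE],
                             kin_meta)
  ord <- order(avg$meta$time)
  scaled <- scale_rows(avg$values[, ord, drop = FALSE],
                       pseudocount = config$signal_pseudocount)
  clusters <- cluster_kinetics(scaled, times = avg$meta$time[ord],
                               k_candidates = config$kmeans_k,
                               seed = config$seed)

  # stage 4: dose sensitivity of GAS vs ISRE peaks (1 h, low vs high dose)
  doses <- sort(unique(meta$dose[meta$parsed & meta$time > 0]))
  dose <- NULL
  if (length(doses) >= 2) {
    dose_time <- 1
    if (!any(meta$parsed & meta$time == dose_time))
      dose_time <- min(meta$time[meta$parsed & meta$time > 0])
    lfc_low <- signal_log2fc(inputs$signal, "beta", doses[1], dose_time,
                             config$signal_pseudocount)
    lfc_high <- signal_log2fc(inputs$signal, "beta", doses[length(doses)],
                              dose_time, config$signal_pseudocount)
    gas <- ipeaks$peak[ipeaks$category == "GAS"]
    isre <- ipeaks$peak[ipeaks$category == "ISRE"]
    dose <- list(
      gas = if (length(gas)) dose_comparison(lfc_low[gas], lfc_high[gas]),
      isre = if (length(isre)) dose_comparison(lfc_low[isre], lfc_high[isre]),
      time = dose_time, doses = range(doses)
    )
  }

  # stage 5: expression normalization, expressed filter, ISG calling
  norm <- normalize_counts(inputs$counts, inputs$gene_lengths)
  expressed <- filter_expressed(norm, config$cpm_filter)
  emeta <- norm$conditions
  basal_cols <- emeta$column[emeta$parsed & emeta$time == 0]
  stim_dose <- max(emeta$dose[emeta$parsed & emeta$stimulus == "beta"])
  stim_cols <- select_condition(norm, "beta", dose = stim_dose)
  isgs <- call_isgs(norm, stim_cols, basal_cols, fdr = config$isg_fdr,
                    fold = config$isg_fold,
                    pseudocount = config$rpkm_pseudocount, genes = expressed)
  isg_genes <- isgs$gene_id[isgs$isg]

  # stage 6: link motif-categorized inducible peaks to closest expressed genes
  mpeaks <- ipeaks[ipeaks$category != "NO_MOTIF", , drop = FALSE]
  links <- link_peaks(mpeaks, inputs$tss, expressed = expressed,
                      promoter_window = config$promoter_window)
  gene_table <- unique_gene_table(links)
  link_counts <- link_summary(gene_table)

  # stage 7: induced fraction of linked genes by peak category
  induced_by_category <- lapply(split(gene_table$gene_id, gene_table$category),
    function(gg) induced_fraction(gg, norm, stim_cols, basal_cols,
                                  fold = config$isg_fold,
                                  pseudocount = config$rpkm_pseudocount))

  # stage 8: enhancement analysis on the ISG set (requires the mixing design)
  records <- NULL; comparison <- NULL; es_motif <- NULL; quartiles <- NULL
  mixed_cols <- select_condition(norm, "mixed")
  gamma_cols <- select_condition(norm, "gamma")
  beta_low_cols <- select_condition(
    norm, "beta", dose = min(emeta$dose[emeta$parsed & emeta$stimulus == "beta"]))
  if (length(mixed_cols) && length(gamma_cols) && length(isg_genes) >= 4) {
    records <- enhancement_records(
      norm, isg_genes, mixed_cols, beta_low_cols, gamma_cols, basal_cols,
      gene_table = gene_table, genome = inputs$genome, tss = inputs$tss,
      gc_window = config$gc_window, pseudocount = config$rpkm_pseudocount)
    quartiles <- attr(records, "partition")
    comparison <- compare_quartiles(records)
    es_motif <- es_by_promoter_motif(records)
  }

  manifest <- list(
    config = unclass(config),
    n_peaks_input = nrow(inputs$peaks),
    n_inducible = sum(inducible),
    category_counts = as.list(table(ipeaks$category)),
    cluster_k = clusters$k,
    cluster_sizes = as.list(table(clusters$labels)),
    n_expressed = length(expressed),
    n_isgs = length(isg_genes),
    n_linked_genes = nrow(gene_table),
    n_promoter_linked = sum(gene_table$promoter),
    quartile_size = if (!is.null(quartiles)) quartiles$q else NA_integer_
  )

  run <- structure(list(
    classification = classification, inducible = inducible,
    clusters = clusters, dose = dose, norm = norm, expressed = expressed,
    isgs = isgs, isg_genes = isg_genes, links = links,
    gene_table = gene_table, link_counts = link_counts,
    induced_by_category = induced_by_category, records = records,
    quartiles = quartiles, comparison = comparison,
    es_by_motif = es_motif, manifest = manifest, config = config
  ), class = "ifn_run")

  if (!is.null(outdir)) .write_run(run, outdir)
  run
}

.write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(run$classification, "peak_categories.tsv")
  wt(data.frame(peak = names(run$inducible), inducible = run$inducible,
                cluster = run$clusters$labels[names(run$inducible)]),
     "inducible_peaks.tsv")
  wt(run$isgs, "isg_calls.tsv")
  wt(run$links, "peak_gene_links.tsv")
  wt(run$gene_table, "unique_gene_table.tsv")
  wt(run$link_counts, "link_summary.tsv")
  if (!is.null(run$records)) wt(as.data.frame(run$records), "enhancement_records.tsv")
  manifest <- run$manifest
  manifest$output_files <- list.files(outdir)
  manifest$file_digests <- as.list(tools::md5sum(
    list.files(outdir, full.names = TRUE)))
  names(manifest$file_digests) <- basename(names(manifest$file_digests))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}

#' @export
print.ifn_run <- function(x, ...) {
  m <- x$manifest
  cat("Interferon STAT1 pipeline run\n")
  cat(sprintf("  peaks: %d input, %d inducible\n", m$n_peaks_input, m$n_inducible))
  cat("  categories: ",
      paste(names(m$category_counts), unlist(m$category_counts),
            sep = "=", collapse = ", "), "\n", sep = "")
  cat(sprintf("  kinetic clusters: k = %d (sizes %s)\n", m$cluster_k,
              paste(unlist(m$cluster_sizes), collapse = ", ")))
  cat(sprintf("  expressed genes: %d; ISGs: %d\n", m$n_expressed, m$n_isgs))
  cat(sprintf("  uniquely linked genes: %d (%d promoter, %d distal)\n",
              m$n_linked_genes, m$n_promoter_linked,
              m$n_linked_genes - m$n_promoter_linked))
  if (!is.null(x$records))
    cat(sprintf("  enhancement quartiles: %d genes per tail\n", m$quartile_size))
  invisible(x)
}

#' @export
summary.ifn_run <- function(object, ...) {
  print(object)
  for (cc in names(object$induced_by_category)) {
    f <- object$induced_by_category[[cc]]
    cat(sprintf("  induced > %g-fold among %s-linked genes: %d/%d (%d%%)\n",
                object$config$isg_fold, cc, f$count, f$total, f$percent))
  }
  if (!is.null(object$dose)) {
    cat(sprintf("  dose gate: GAS high>low p = %.3g; ISRE high>low p = %.3g\n",
                object$dose$gas$high_vs_low$p_value,
                object$dose$isre$high_vs_low$p_value))
  }
  if (!is.null(object$comparison)) print(object$comparison)
  invisible(object)
}

#' Evaluate a pipeline run against planted truth
#'
#' Recovery metrics for a run on synthetic data: inducible-peak
#' sensitivity/specificity, per-peak category accuracy, adjusted Rand index
#' of the kinetic clustering against the planted classes, peak-gene link
#' accuracy, and ISG recall/precision.
#'
#' @param run An `"ifn_run"`.
#' @param sim The `"ifn_simulation"` the run was computed on.
#' @return A list of named metrics.
#' @export
evaluate_against_truth <- function(run, sim) {
  tp <- sim$chip$truth_peaks
  tg <- sim$rna$truth_genes
  ind <- run$inducible[tp$peak]
  sens <- sum(ind & tp$inducible) / sum(tp$inducible)
  spec <- sum(!ind & !tp$inducible) / sum(!tp$inducible)
  cl <- run$classification
  truth_cat <- tp$category[match(cl$peak, tp$peak)]
  cat_acc <- mean(cl$category == truth_cat)
  called <- names(run$clusters$labels)
  truth_kin <- tp$kinetic_class[match(called, tp$peak)]
  usable <- truth_kin %in% c("early", "late")
  ari <- mclust::adjustedRandIndex(run$clusters$labels[usable],
                                   truth_kin[usable])
  # cluster 1 should be the early class
  early_match <- mean(
    (run$clusters$labels[usable] == 1) == (truth_kin[usable] == "early"))
  gt <- run$gene_table
  truth_links <- tg[tg$gene_id %in% gt$gene_id & !is.na(tg$linked_peak), ,
                    drop = FALSE]
  link_acc <- mean(gt$peak[match(truth_links$gene_id, gt$gene_id)] ==
                     truth_links$linked_peak)
  truth_isg <- tg$gene_id[tg$isg]
  isg_recall <- mean(truth_isg %in% run$isg_genes)
  isg_precision <- if (length(run$isg_genes))
    mean(run$isg_genes %in% truth_isg) else NA_real_
  list(inducible_sensitivity = sens, inducible_specificity = spec,
       category_accuracy = cat_acc, cluster_ari = ari,
       cluster1_is_early = early_match, link_accuracy = link_acc,
       isg_recall = isg_recall, isg_precision = isg_precision)
}
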