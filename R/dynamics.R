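# Average replicate columns of a signal matrix within (stimulus, dose, time)
# groups. Returns the averaged matrix plus the group metadata.
.average_replicates <- function(signal, meta) {
  meta <- meta[meta$parsed, , drop = FALSE]
  key <- paste(meta$stimulus, meta$dose, meta$time, sep = "|")
  groups <- split(meta$column, key)
  ukey <- names(groups)
  avg <- vapply(ukey, function(k) {
    rowMeans(signal[, groups[[k]], drop = FALSE])
  }, numeric(nrow(signal)))
  avg <- matrix(avg, nrow = nrow(signal),
                dimnames = list(rownames(signal), ukey))
  info <- do.call(rbind, strsplit(ukey, "|", fixed = TRUE))
  list(values = avg,
       meta = data.frame(key = ukey, stimulus = info[, 1],
                         dose = as.numeric(info[, 2]),
                         time = as.numeric(info[, 3]),
                         stringsAsFactors = FALSE))
}

#' Identify inducible peaks from a normalized signal matrix
#'
#' A peak is inducible when its pseudocounted signal ratio over the basal
#' condition reaches `fold` in at least `min_timepoints` stimulated
#' condition-timepoints. Replicate columns of the same (stimulus, dose,
#' time) are averaged before the test; the basal condition is the set of
#' columns with time 0. Columns named in `exclude_cols` (e.g. an outlier
#' replicate) are dropped from the test but remain in the matrix.
#'
#' @param signal Numeric matrix, peaks x conditions, depth-normalized tag
#'   counts with parseable column names (see [parse_conditions()]).
#' @param fold Fold threshold (> 1).
#' @param min_timepoints Minimum number of stimulated condition-timepoints
#'   at or above `fold`.
#' @param pseudocount Pseudocount `c` added to numerator and denominator.
#' @param exclude_cols Character vector of column names to exclude.
#' @return A logical vector named by peak, `TRUE` for inducible peaks.
#' @export
find_inducible <- function(signal, fold = 2, min_timepoints = 2,
                           pseudocount = 1, exclude_cols = character()) {
  stopifnot(is.matrix(signal), fold > 1, min_timepoints >= 1)
  meta <- parse_conditions(colnames(signal))
  keep <- !(meta$column %in% exclude_cols)
  avg <- .average_replicates(signal[, keep, drop = FALSE], meta[keep, , drop = FALSE])
  basal_idx <- which(avg$meta$time == 0)
  if (length(basal_idx) == 0L) stop("no basal (time 0) column in signal matrix")
  stim_idx <- which(avg$meta$time > 0)
  if (length(stim_idx) == 0L) stop("no stimulated columns left after exclusion")
  basal <- rowMeans(avg$values[, basal_idx, drop = FALSE])
  ratios <- (avg$values[, stim_idx, drop = FALSE] + pseudocount) /
    (basal + pseudocount)
  hits <- rowSums(ratios >= fold)
  out <- hits >= min_timepoints
  names(out) <- rownames(signal)
  out
}

#' Row-wise z-scores of log2 signal
#'
#' Transforms each value to log2(value + pseudocount) and standardizes each
#' row to mean 0 and population standard deviation 1 (the scaling applied
#' before kinetic clustering). Constant rows map to all zeros.
#'
#' @param x Numeric matrix with at least two columns.
#' @param pseudocount Pseudocount added before the log.
#' @return Matrix of the same shape.
#' @export
scale_rows <- function(x, pseudocount = 1) {
  stopifnot(is.matrix(x), ncol(x) >= 2)
  z <- log2(x + pseudocount)
  mu <- rowMeans(z)
  sd_pop <- sqrt(rowMeans((z - mu)^2))
  out <- (z - mu) / ifelse(sd_pop == 0, 1, sd_pop)
  out[sd_pop == 0, ] <- 0
  out
}

# mean silhouette width over all points for a labelling (Euclidean distance)
.mean_silhouette <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  k <- sort(unique(labels))
  if (length(k) < 2L) return(NA_real_)
  sil <- numeric(length(labels))
  for (i in seq_along(labels)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) sum(d[i, own]) / (sum(own) - 1L) else 0
    b <- min(vapply(k[k != labels[i]], function(g)
      mean(d[i, labels == g]), 0))
    denom <- max(a, b)
    sil[i] <- if (denom == 0) 0 else (b - a) / denom
  }
  mean(sil)
}

#' Cluster binding kinetics by k-means with silhouette-based k selection
#'
#' Runs k-means (25 random restarts, fixed seed) on row-scaled log2 signal
#' for each candidate k and keeps the k with the largest mean silhouette
#' width. Cluster labels are renumbered so that cluster 1 is the *early*
#' cluster: clusters are ordered by their signal-weighted mean time, using
#' each cluster's mean scaled profile shifted to be non-negative as the
#' weight.
#'
#' @param scaled Numeric matrix of row-scaled profiles (peaks x timepoints),
#'   e.g. from [scale_rows()].
#' @param times Numeric vector of timepoints (hours), one per column.
#' @param k_candidates Integer vector of candidate cluster numbers (all
#'   >= 2).
#' @param seed Integer seed for the restarts.
#' @param nstart Number of random restarts per k.
#' @return An object of class `"kinetic_clusters"`: list with `labels`
#'   (integer vector named by row), `k`, `silhouette` (named numeric, one
#'   mean width per candidate k), `wss` (total within-cluster sum of
#'   squares per candidate, the elbow curve), `centers`.
#' @export
cluster_kinetics <- function(scaled, times, k_candidates = 2:6, seed = 1L,
                             nstart = 25L) {
  stopifnot(is.matrix(scaled), length(times) == ncol(scaled))
  if (any(k_candidates < 2)) stop("k candidates must all be >= 2")
  n_distinct <- nrow(unique(scaled))
  if (n_distinct < 2L) stop("degenerate input: all rows identical, silhouette undefined")
  if (nrow(scaled) < max(k_candidates) + 1L)
    stop("need at least max(k_candidates)+1 rows")
  fits <- list(); sils <- numeric(0); wss <- numeric(0)
  for (k in k_candidates) {
    if (k > n_distinct) {
      # k-means cannot place k distinct centers; candidate not assessable
      sils[as.character(k)] <- NA_real_
      wss[as.character(k)] <- NA_real_
      next
    }
    set.seed(seed + k)
    km <- stats::kmeans(scaled, centers = k, nstart = nstart, iter.max = 50L)
    fits[[as.character(k)]] <- km
    sils[as.character(k)] <- .mean_silhouette(scaled, km$cluster)
    wss[as.character(k)] <- km$tot.withinss
  }
  if (all(is.na(sils))) stop("no candidate k was assessable")
  best <- names(sils)[which.max(sils)]
  km <- fits[[best]]
  # canonical ordering: cluster 1 = earliest signal-weighted mean time
  centers <- km$centers
  wmean_time <- apply(centers, 1, function(p) {
    w <- p - min(p)
    if (sum(w) == 0) return(mean(times))
    sum(w * times) / sum(w)
  })
  ord <- order(wmean_time)
  relabel <- match(seq_len(nrow(centers)), ord)
  labels <- relabel[km$cluster]
  names(labels) <- rownames(scaled)
  structure(list(labels = labels, k = as.integer(best), silhouette = sils,
                 wss = wss, centers = centers[ord, , drop = FALSE],
                 times = times),
            class = "kinetic_clusters")
}

#' @export
print.kinetic_clusters <- function(x, ...) {
  cat(sprintf("Kinetic clustering: k = %d selected by mean silhouette\n", x$k))
  cat("  silhouette by k: ",
      paste(sprintf("%s=%.3f", names(x$silhouette), x$silhouette), collapse = ", "),
      "\n", sep = "")
  cat("  cluster sizes (1 = early): ",
      paste(table(x$labels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Log2 fold-changes of signal over basal
#'
#' Replicate-averaged, pseudocounted log2 ratio of one stimulated condition
#' over the basal (time 0) condition, for each peak.
#'
#' @param signal Signal matrix with parseable column names.
#' @param stimulus,dose,time Condition selector for the numerator.
#' @param pseudocount Pseudocount for both numerator and denominator.
#' @return Named numeric vector of log2 fold-changes.
#' @export
signal_log2fc <- function(signal, stimulus, dose, time, pseudocount = 1) {
  meta <- parse_conditions(colnames(signal))
  num <- meta$parsed & meta$stimulus == stimulus & meta$dose == dose &
    meta$time == time
  den <- meta$parsed & meta$time == 0
  if (!any(num)) stop("no columns match the requested condition")
  if (!any(den)) stop("no basal (time 0) columns")
  v <- rowMeans(signal[, meta$column[num], drop = FALSE])
  b <- rowMeans(signal[, meta$column[den], drop = FALSE])
  log2((v + pseudocount) / (b + pseudocount))
}

#' Dose-sensitivity test for a peak set
#'
#' One-sided Wilcoxon rank-sum test that induced log2 fold-changes at the
#' high dose exceed those at the low dose, plus paired one-sided tests that
#' each dose's signal exceeds basal.
#'
#' @param low_lfc,high_lfc Numeric vectors of per-peak induced log2
#'   fold-changes (over basal) at the low and high dose.
#' @return A list of class `"dose_comparison"` with `high_vs_low` (an
#'   `"ifn_test"`), `low_vs_basal`, `high_vs_basal` (one-sided signed-rank
#'   style tests of positive induction), and medians.
#' @export
dose_comparison <- function(low_lfc, high_lfc) {
  if (length(low_lfc) == 0L || length(high_lfc) == 0L)
    stop("dose_comparison: both samples must be non-empty")
  res <- list(
    high_vs_low = rank_sum_test(high_lfc, low_lfc, alternative = "greater"),
    low_vs_basal = rank_sum_test(low_lfc, rep(0, length(low_lfc)),
                                 alternative = "greater"),
    high_vs_basal = rank_sum_test(high_lfc, rep(0, length(high_lfc)),
                                  alternative = "greater"),
    median_low = stats::median(low_lfc),
    median_high = stats::median(high_lfc)
  )
  class(res) <- "dose_comparison"
  res
}

#' @export
print.dose_comparison <- function(x, ...) {
  cat("Dose comparison (one-sided rank-sum)\n")
  cat(sprintf("  median log2FC: low %.3f, high %.3f\n", x$median_low, x$median_high))
  cat(sprintf("  high > low: p = %.3g\n", x$high_vs_low$p_value))
  cat(sprintf("  low > basal: p = %.3g; high > basal: p = %.3g\n",
              x$low_vs_basal$p_value, x$high_vs_basal$p_value))
  invisible(x)
}
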