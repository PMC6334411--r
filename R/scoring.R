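#' Score a clustering against ground truth
#'
#' Computes the four benchmark performance parameters used to compare
#' cluster algorithms on synthetic data with known composition:
#' \describe{
#'   \item{n_positive_detected}{number of ground-truth clusters detected;
#'     truth clusters matched to the same detected cluster (fusions) are
#'     counted once}
#'   \item{n_false_clusters}{detected clusters not matching any
#'     ground-truth cluster: fewer than half their members are signal}
#'   \item{pct_noise_clustered}{percentage of true-noise localizations
#'     assigned to any cluster}
#'   \item{pct_signal_clustered}{percentage of true-signal localizations
#'     assigned to any cluster}
#' }
#' The matching rule is majority overlap: a truth cluster is detected iff
#' at least 50% of its members carry one common detected (non-noise)
#' label.
#'
#' @param labeling a `cluster_labeling` or integer label vector
#'   (0 = noise).
#' @param truth integer ground-truth components (0 = noise), or the
#'   `ground_truth` data frame emitted by the synthetic generators (its
#'   `component` column is used).
#' @return A one-row data frame of class `performance_report`.
#' @export
score_clustering <- function(labeling, truth) {
  labels <- if (inherits(labeling, "cluster_labeling")) labeling$labels
            else as.integer(labeling)
  if (is.data.frame(truth)) truth <- truth$component
  truth <- as.integer(truth)
  if (length(labels) != length(truth))
    stop("labeling and ground truth have different lengths")

  truth_ids <- sort(unique(truth[truth > 0L]))
  matched_label <- integer(0)
  for (tc in truth_ids) {
    memb <- labels[truth == tc]
    nz <- memb[memb > 0L]
    if (length(nz) == 0L) next
    counts <- table(nz)
    best <- as.integer(names(counts))[which.max(counts)]
    if (max(counts) >= 0.5 * length(memb))
      matched_label <- c(matched_label, best)
  }
  n_positive <- length(unique(matched_label))

  det_ids <- sort(unique(labels[labels > 0L]))
  n_false <- 0L
  for (dc in det_ids) {
    memb_truth <- truth[labels == dc]
    if (mean(memb_truth > 0L) < 0.5) n_false <- n_false + 1L
  }

  is_noise <- truth == 0L
  pct_noise <- if (any(is_noise)) 100 * mean(labels[is_noise] > 0L) else 0
  pct_signal <- if (any(!is_noise)) 100 * mean(labels[!is_noise] > 0L) else 0

  out <- data.frame(n_positive_detected = n_positive,
                    n_false_clusters = n_false,
                    pct_noise_clustered = pct_noise,
                    pct_signal_clustered = pct_signal)
  class(out) <- c("performance_report", "data.frame")
  out
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(paste0("<performance_report> %d true cluster(s) detected, ",
                     "%d false; %.1f%% of noise and %.1f%% of signal clustered\n"),
              x$n_positive_detected, x$n_false_clusters,
              x$pct_noise_clustered, x$pct_signal_clustered))
  invisible(x)
}
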