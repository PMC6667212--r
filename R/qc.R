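#' Between-sample Euclidean distance matrix
#'
#' Pairwise Euclidean distances between sample columns of a transformed
#' expression matrix (typically the output of [rlog_like()]).
#'
#' @param mat transformed matrix, genes x samples
#' @return symmetric distance matrix with zero diagonal
#' @export
sample_distances <- function(mat) {
  if (anyNA(mat)) stopf("transformed matrix contains missing values")
  as.matrix(stats::dist(t(mat)))
}

#' PCA of samples
#'
#' Gene-centred singular value decomposition of a transformed expression
#' matrix, samples as observations. Component signs follow a deterministic
#' convention: the largest-magnitude gene loading of each component is
#' positive.
#'
#' @param mat transformed matrix, genes x samples
#' @param n_components number of components to return (at most samples - 1)
#' @return list with `scores` (samples x components), `rotation` (genes x
#'   components) and `variance_fraction`
#' @export
pca_scores <- function(mat, n_components = 2L) {
  n <- ncol(mat)
  if (n < 2L) stopf("PCA needs at least 2 samples")
  if (n_components > n - 1L)
    stopf("n_components must be <= samples - 1 (= %d)", n - 1L)
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- seq_len(n_components)
  scores <- pc$x[, keep, drop = FALSE]
  rot <- pc$rotation[, keep, drop = FALSE]
  for (j in keep) {
    flip <- sign(rot[which.max(abs(rot[, j])), j])
    if (flip < 0) { rot[, j] <- -rot[, j]; scores[, j] <- -scores[, j] }
  }
  list(scores = scores, rotation = rot, variance_fraction = varfrac[keep])
}

#' Flag replicate outliers by within-stage distance
#'
#' Within each (tissue, stage) group of at least 3 replicates, each sample's
#' median distance to the other replicates is computed; a sample is flagged
#' when that distance exceeds a multiple (default 2) of the group median of
#' these per-sample distances (a robust centre a single bad replicate cannot
#' drag). Advisory only: nothing is removed.
#'
#' @param dists distance matrix from [sample_distances()]
#' @param samples sample sheet (`sample`, `tissue`, `stage`, `replicate`)
#' @param multiple flagging multiple of the group median distance
#' @return character vector of flagged sample ids
#' @export
flag_outlier_samples <- function(dists, samples, multiple = 2) {
  flagged <- character()
  groups <- split(samples$sample, paste(samples$tissue, samples$stage))
  for (g in groups) {
    if (length(g) < 3L) next
    d <- dists[g, g, drop = FALSE]
    med_i <- vapply(seq_along(g), function(i) stats::median(d[i, -i]), 1)
    ref <- stats::median(med_i)
    if (ref <= 0) next
    flagged <- c(flagged, g[med_i > multiple * ref])
  }
  flagged
}

#' Replicate-quality report
#'
#' Runs the QC stage on a count matrix: variance-stabilised transform,
#' per-sample distribution summaries, between-sample distances, PCA and
#' replicate outlier flags. Counts are never modified.
#'
#' @param cm a [count_matrix()]
#' @param n_components PCA components to report
#' @param multiple outlier flagging multiple (see [flag_outlier_samples()])
#' @return object of class `qc_report`
#' @export
qc_report <- function(cm, n_components = 2L, multiple = 2) {
  mat <- rlog_like(cm)
  dists <- sample_distances(mat)
  pca <- pca_scores(mat, n_components = min(n_components, ncol(mat) - 1L))
  summaries <- t(apply(mat, 2L, stats::quantile, probs = c(0, 0.25, 0.5, 0.75, 1)))
  structure(list(summaries = summaries, distances = dists, pca = pca,
                 flagged = flag_outlier_samples(dists, cm$samples, multiple)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d samples\n", nrow(x$summaries)))
  cat(sprintf("  PC variance fractions: %s\n",
              paste(sprintf("%.2f", x$pca$variance_fraction), collapse = ", ")))
  if (length(x$flagged))
    cat("  flagged samples:", paste(x$flagged, collapse = ", "), "\n")
  else cat("  no replicate outliers flagged\n")
  invisible(x)
}
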