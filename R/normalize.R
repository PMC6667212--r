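#' Remove weakly covered genes
#'
#' Keeps genes whose count reaches `min_count` in at least one sample. With
#' `min_count = 0` this is the identity.
#'
#' @param cm a [count_matrix()]
#' @param min_count minimum count required in some sample
#' @export
filter_low_counts <- function(cm, min_count = 1L) {
  if (min_count < 0) stopf("min_count must be >= 0")
  keep <- apply(cm$counts, 1L, max) >= min_count
  cm$counts <- cm$counts[keep, , drop = FALSE]
  cm
}

#' Trimmed-mean-of-M-values (TMM) size factors
#'
#' Between-sample scaling factors combining library size with a TMM adjustment
#' computed against a reference sample (the one whose upper-quartile
#' count fraction is closest to the mean upper quartile). For each sample,
#' log2 count-fraction ratios (M) and average log intensities (A) are formed
#' over genes expressed in both the sample and the reference; the most extreme
#' 30% of M-values and 5% of A-values are trimmed from each tail and the remaining M-values
#' averaged with asymptotic inverse-variance (delta-method binomial) weights.
#' Factors are library size times the trimmed-mean adjustment, rescaled so
#' their geometric mean is 1: a sample whose column is a doubled copy of
#' another gets twice its factor.
#'
#' @param cm a [count_matrix()]
#' @param logratio_trim,abs_trim total trim fractions for M and A values
#' @return object of class `norm_factors`: named numeric vector of per-sample
#'   factors with attribute `method = "TMM"`
#' @export
tmm_factors <- function(cm, logratio_trim = 0.3, abs_trim = 0.05) {
  x <- cm$counts
  if (ncol(x) < 2L) stopf("TMM needs at least 2 samples")
  lib <- colSums(x)
  if (any(lib <= 0)) stopf("sample with zero total count: %s", colnames(x)[lib <= 0][1L])
  f75 <- apply(sweep(x, 2L, lib, "/"), 2L, stats::quantile, probs = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  adj <- vapply(seq_len(ncol(x)), function(k) {
    if (k == ref) return(1)
    2^tmm_one(x[, k], x[, ref], lib[k], lib[ref], logratio_trim, abs_trim)
  }, 1)
  fac <- lib * adj
  fac <- fac / geometric_mean(fac)
  structure(stats::setNames(fac, colnames(x)), method = "TMM", class = "norm_factors")
}

# trimmed weighted mean of M-values of sample `obs` against reference `ref`;
# trim fractions are removed from each tail, the canonical TMM rule
tmm_one <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
  pos <- obs > 0 & ref > 0
  if (!any(pos))
    stopf("sample shares no co-expressed genes with the TMM reference")
  obs <- obs[pos]; ref <- ref[pos]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a) & w > 0
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (!length(m)) return(0)
  if (max(abs(m)) < 1e-6) return(0)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_trim) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(0)
  sum(m[keep] / w[keep]) / sum(1 / w[keep])
}

#' Relative-log-expression (median-of-ratios) size factors
#'
#' Per-sample factor is the median, over genes expressed in every sample, of
#' the ratio of the gene's count to its geometric mean across samples.
#'
#' @param cm a [count_matrix()]
#' @return a `norm_factors` vector with attribute `method = "RLE"`
#' @export
rle_size_factors <- function(cm) {
  x <- cm$counts
  pos <- rowSums(x > 0) == ncol(x)
  if (!any(pos))
    stopf("no gene has positive counts in all samples; filter or merge samples first")
  lg <- log(x[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  fac <- apply(exp(lg - geo), 2L, stats::median)
  structure(stats::setNames(fac, colnames(x)), method = "RLE", class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat(sprintf("%s size factors:\n", attr(x, "method")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Variance-stabilising log transform for QC
#'
#' log2(normalized count + 1) with per-gene shrinkage of each sample's value
#' toward the gene mean; the shrinkage weight `prior / (prior + mean)` grows
#' as the gene's mean normalized count falls, so weakly covered genes are
#' flattened toward their mean while high-count genes converge to the plain
#' log transform. Used only by the QC stage.
#'
#' @param cm a [count_matrix()]
#' @param prior shrinkage half-weight point on the mean-count scale
#' @return matrix of transformed values, genes x samples
#' @export
rlog_like <- function(cm, prior = 10) {
  sf <- rle_size_factors(cm)
  z <- sweep(cm$counts, 2L, as.numeric(sf), "/")
  lg <- log2(z + 1)
  mu <- rowMeans(z)
  w <- prior / (prior + mu)
  (1 - w) * lg + w * rowMeans(lg)
}

#' log2 counts-per-million on effective library sizes
#' @param counts count matrix (plain matrix)
#' @param eff_lib effective library sizes
#' @keywords internal
log_cpm <- function(counts, eff_lib) {
  log2(sweep(counts + 0.5, 2L, eff_lib + 1, "/") * 1e6)
}
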