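#' Precision-weighted moderated-t caller
#'
#' Two-group linear model on log2 counts-per-million in the
#' voom/moderated-t lineage. Counts are converted to log2-CPM with a 0.5
#' offset on TMM-effective library sizes; a first unweighted genewise fit
#' yields the mean-variance relation, smoothed by a locally weighted
#' regression of the square root of residual standard deviation on mean
#' log2-count; precision weights evaluated at each observation's fitted
#' log2-count feed a weighted refit; residual variances are then moderated by
#' empirical Bayes, with the prior degrees of freedom and prior variance
#' obtained by moment-matching the scaled-F distribution of the genewise
#' variances, and the group effect tested with a moderated t on
#' residual-plus-prior degrees of freedom.
#'
#' @param cm a [count_matrix()] covering one tissue
#' @param test,ref stage labels
#' @param config a [pipeline_config()]; `lowess_span` controls the
#'   mean-variance smoother
#' @param use_weights disable (for diagnostics) the precision weights
#' @param prior_df override the estimated prior degrees of freedom; `0` turns
#'   moderation off, reducing the caller to an ordinary genewise t-test
#' @return data frame `gene`, `lfc`, `p`, `flag`
#' @export
voom_lm_test <- function(cm, test, ref, config = pipeline_config(),
                         use_weights = TRUE, prior_df = NULL) {
  cs <- contrast_subset(cm, test, ref)
  y <- cs$counts
  n <- ncol(y)
  df_resid <- n - 2L
  if (df_resid < 1L)
    stopf("contrast %s vs %s leaves no residual degrees of freedom", test, ref)
  eff_lib <- as.numeric(tmm_factors(cs$cm)) * geometric_mean(colSums(y))
  Y <- log_cpm(y, eff_lib)
  x <- as.numeric(cs$group)

  first <- wls_two_group(Y, x, matrix(1, nrow(Y), n))
  # mean-variance trend on the log2-count scale
  sx <- rowMeans(Y) + mean(log2(eff_lib + 1)) - log2(1e6)
  sy <- sqrt(sqrt(first$s2))
  if (use_weights) {
    lo <- stats::lowess(sx, sy, f = config$lowess_span)
    trend <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
    fitted_cpm <- outer(first$b0, rep(1, n)) + outer(first$b1, x)
    fitted_count <- sweep(fitted_cpm, 2L, log2(eff_lib + 1) - log2(1e6), "+")
    w <- 1 / pmax(trend(fitted_count), 1e-4)^4
    w <- matrix(w, nrow(Y), n)
  } else {
    w <- matrix(1, nrow(Y), n)
  }
  fit <- wls_two_group(Y, x, w)

  mod <- moderate_variances(fit$s2, df_resid, prior_df = prior_df)
  tstat <- fit$b1 / sqrt(mod$s2_post * fit$unscaled_var1)
  df_total <- df_resid + mod$df_prior
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  data.frame(gene = rownames(y), lfc = fit$b1, p = p, flag = "",
             stringsAsFactors = FALSE, row.names = NULL)
}

# vectorized weighted least squares for the two-group design, all genes at
# once; returns coefficients, residual variance and the unscaled variance of
# the group coefficient.
wls_two_group <- function(Y, x, w) {
  n <- ncol(Y)
  xr <- matrix(x, nrow(Y), n, byrow = TRUE)
  s0 <- rowSums(w); s1 <- rowSums(w * xr)
  t0 <- rowSums(w * Y); t1 <- rowSums(w * Y * xr)
  det <- s0 * s1 - s1^2
  b1 <- (s0 * t1 - s1 * t0) / det
  b0 <- (t0 - s1 * b1) / s0
  resid <- Y - (b0 + b1 * xr)
  s2 <- rowSums(w * resid^2) / (n - 2L)
  list(b0 = b0, b1 = b1, s2 = s2, unscaled_var1 = s0 / det)
}

#' Empirical-Bayes variance moderation
#'
#' Moment-matching fit of a scaled-F model to genewise residual variances:
#' on the log scale, the excess spread of `log(s2)` beyond what the residual
#' degrees of freedom explain determines the prior degrees of freedom (via the
#' inverse trigamma), and the recentred mean determines the prior variance.
#' The moderated variance is the degrees-of-freedom-weighted average of
#' genewise and prior variance, so it always lies between them.
#'
#' @param s2 genewise residual variances
#' @param df residual degrees of freedom (scalar)
#' @param prior_df optional override; `0` disables moderation, `Inf` collapses
#'   every variance to the prior
#' @return list with `s2_post`, `df_prior`, `s2_prior`
#' @export
moderate_variances <- function(s2, df, prior_df = NULL) {
  ok <- is.finite(s2) & s2 > 0
  zed <- log(s2[ok])
  e <- zed - digamma(df / 2) + log(df / 2)
  if (is.null(prior_df)) {
    evar <- stats::var(e) - trigamma(df / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(mean(e))
    }
  } else {
    d0 <- prior_df
    s02 <- if (is.finite(d0) && d0 > 0)
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)) else exp(mean(e))
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + df * s2) / (d0 + df)
  list(s2_post = s2_post, df_prior = d0, s2_prior = s02)
}

# Newton solve of trigamma(x) = y
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < 1e-8 * x) break
  }
  x
}
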