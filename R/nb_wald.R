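#' Negative-binomial GLM Wald test
#'
#' Two-group NB regression in the GLM-Wald lineage of count-based DE
#' analysis. Counts are modelled with a log link, a group indicator and
#' log median-of-ratios (RLE) size factors as offsets. The genewise
#' method-of-moments dispersion is shrunk, on the log scale, toward a fitted
#' mean-dispersion trend `alpha(mu) = a0 + a1 / mu`; the model is fit by
#' Fisher-scoring IRLS and the group coefficient tested with a Wald z from the
#' information matrix at convergence.
#'
#' @param cm a [count_matrix()] covering one tissue
#' @param test,ref stage labels
#' @param config a [pipeline_config()]; `irls_maxit` / `irls_tol` control the
#'   fit, `fixed_dispersion` is the fallback for unreplicated contrasts
#' @param dispersion optional fixed dispersion (scalar or per-gene), bypassing
#'   estimation and trend shrinkage
#' @param prior_df prior degrees of freedom of the trend shrinkage
#' @return data frame `gene`, `lfc`, `se`, `p`, `flag` (flags:
#'   `"nonconverged"` genes get p = 1)
#' @export
nb_wald_test <- function(cm, test, ref, config = pipeline_config(),
                         dispersion = NULL, prior_df = 10) {
  cs <- contrast_subset(cm, test, ref)
  y <- cs$counts
  sf <- as.numeric(rle_size_factors(cs$cm))
  z <- sweep(y, 2L, sf, "/")

  flag <- rep("", nrow(y))
  if (!is.null(dispersion)) {
    alpha <- rep(dispersion, length.out = nrow(y))
  } else if (cs$unreplicated) {
    if (is.null(config$fixed_dispersion))
      stopf(paste("contrast %s vs %s is unreplicated; supply `dispersion` or set",
                  "`fixed_dispersion` in the config"), test, ref)
    alpha <- rep(config$fixed_dispersion, nrow(y))
    flag <- rep("unreplicated", nrow(y))
  } else {
    alpha <- trended_dispersion(z, cs$group, prior_df = prior_df)
    if (cs$n_test < 2L || cs$n_ref < 2L) flag <- rep("unreplicated", nrow(y))
  }

  fit <- nb_irls_two_group(y, cs$group, offset = log(sf), alpha = alpha,
                           maxit = config$irls_maxit, tol = config$irls_tol)
  lfc <- fit$beta1 / log(2)
  se <- fit$se1 / log(2)
  zstat <- ifelse(fit$se1 > 0, fit$beta1 / fit$se1, 0)
  p <- 2 * stats::pnorm(-abs(zstat))
  p[!fit$converged] <- 1
  flag[!fit$converged] <- trimws(paste(flag[!fit$converged], "nonconverged"))
  allzero <- rowSums(y) == 0
  p[allzero] <- 1; lfc[allzero] <- 0
  data.frame(gene = rownames(y), lfc = lfc, se = se, p = p, flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

# genewise MoM dispersion shrunk (in log space) toward the fitted trend
# alpha(mu) = a0 + a1/mu
trended_dispersion <- function(z, group, prior_df = 10) {
  mom <- mom_dispersion(z, group)
  mu <- rowMeans(z)
  gw <- mom$genewise
  ok <- !is.na(gw) & gw > 1e-6 & mu > 0
  if (sum(ok) >= 10) {
    fit <- stats::lm(gw[ok] ~ I(1 / mu[ok]))
    a0 <- max(1e-6, unname(stats::coef(fit)[1L]))
    a1 <- max(0, unname(stats::coef(fit)[2L]))
  } else {
    a0 <- if (is.na(mom$common)) 0.1 else mom$common
    a1 <- 0
  }
  trend <- pmax(1e-6, a0 + a1 / pmax(mu, 1e-8))
  gw_f <- ifelse(is.na(gw), trend, pmax(gw, 1e-6))
  w <- mom$df / (mom$df + prior_df)
  pmax(1e-6, exp(w * log(gw_f) + (1 - w) * log(trend)))
}

# vectorized Fisher-scoring IRLS for the two-group NB log-linear model,
# all genes at once. beta1 is the natural-log fold change test/ref.
nb_irls_two_group <- function(y, group, offset, alpha, maxit = 50L, tol = 1e-8) {
  n_g <- nrow(y)
  x <- as.numeric(group)
  m_test <- rowMeans(sweep(y, 2L, exp(offset), "/")[, x == 1, drop = FALSE])
  m_ref <- rowMeans(sweep(y, 2L, exp(offset), "/")[, x == 0, drop = FALSE])
  b0 <- log(m_ref + 0.1)
  b1 <- pmin(20, pmax(-20, log((m_test + 0.1) / (m_ref + 0.1))))
  dev_old <- rep(Inf, n_g)
  converged <- rep(FALSE, n_g)
  S0 <- S1 <- T0 <- T1 <- rep(NA_real_, n_g)
  xr <- matrix(x, n_g, length(x), byrow = TRUE)
  off <- matrix(offset, n_g, length(x), byrow = TRUE)
  for (it in seq_len(maxit)) {
    act <- which(!converged)
    if (!length(act)) break
    eta <- pmin(b0[act] + b1[act] * xr[act, , drop = FALSE] + off[act, , drop = FALSE], 50)
    mu <- exp(eta)
    a <- alpha[act]
    w <- mu / (1 + a * mu)
    zz <- eta - off[act, , drop = FALSE] + (y[act, , drop = FALSE] - mu) / mu
    s0 <- rowSums(w); s1 <- rowSums(w * xr[act, , drop = FALSE])
    t0 <- rowSums(w * zz); t1 <- rowSums(w * zz * xr[act, , drop = FALSE])
    det <- s0 * s1 - s1^2                       # sxx == s1 for a 0/1 covariate
    ok <- det > 1e-12 & s0 > 1e-12
    b1_new <- ifelse(ok, (s0 * t1 - s1 * t0) / det, b1[act])
    b1_new <- pmin(20, pmax(-20, b1_new))
    b0_new <- ifelse(ok, (t0 - s1 * b1_new) / s0, b0[act])
    b0[act] <- b0_new; b1[act] <- b1_new
    eta <- pmin(b0[act] + b1[act] * xr[act, , drop = FALSE] + off[act, , drop = FALSE], 50)
    mu <- exp(eta)
    yy <- y[act, , drop = FALSE]
    dev <- 2 * rowSums(ifelse(yy > 0, yy * log(yy / mu), 0) -
                         (yy + 1 / a) * log((1 + a * yy) / (1 + a * mu)))
    done <- abs(dev - dev_old[act]) < tol * (abs(dev) + 0.1)
    S0[act] <- s0; S1[act] <- s1
    converged[act[done]] <- TRUE
    dev_old[act] <- dev
  }
  # information matrix at the final iterate (recompute for all genes)
  eta <- pmin(b0 + b1 * xr + off, 50)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  s0 <- rowSums(w); s1 <- rowSums(w * xr)
  det <- pmax(s0 * s1 - s1^2, 1e-300)
  se1 <- sqrt(s0 / det)
  list(beta0 = b0, beta1 = b1, se1 = se1, converged = converged)
}
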