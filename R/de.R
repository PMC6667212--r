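# Shared differential-expression plumbing: contrast subsetting, BH adjustment,
# significance calls, and the per-scheme driver over the three callers.

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with input validation; kept as a
#' named operation because every caller and the enrichment stage share it.
#' @param p vector of p-values in \[0, 1\]
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call a gene up, down or not significant
#'
#' `up` iff lfc >= +threshold and FDR <= cutoff; `down` iff lfc <= -threshold
#' and FDR <= cutoff; `ns` otherwise (defaults: 2-fold, 5% FDR).
#' @param lfc log2 fold changes
#' @param fdr BH-adjusted p-values
#' @param config a [pipeline_config()]
#' @return character vector in `c("up", "down", "ns")`
#' @export
call_deg <- function(lfc, fdr, config = pipeline_config()) {
  sig <- fdr <= config$fdr_threshold
  ifelse(sig & lfc >= config$lfc_threshold, "up",
         ifelse(sig & lfc <= -config$lfc_threshold, "down", "ns"))
}

# subset a count matrix to one contrast; returns counts, group indicator and
# replication bookkeeping. `group` is 1 for test samples, 0 for reference.
contrast_subset <- function(cm, test, ref) {
  if (length(unique(cm$samples$tissue)) > 1L)
    stopf("count matrix spans several tissues; subset to one before testing")
  test <- as.character(test); ref <- as.character(ref)
  for (s in c(test, ref)) if (!s %in% cm$samples$stage)
    stopf("stage %s absent from the count matrix", s)
  keep <- cm$samples$stage %in% c(test, ref)
  sub <- subset_samples(cm, keep)
  group <- as.integer(sub$samples$stage == test)
  n_test <- sum(group); n_ref <- sum(group == 0L)
  list(counts = sub$counts, cm = sub, group = group,
       n_test = n_test, n_ref = n_ref,
       unreplicated = max(n_test, n_ref) < 2L)
}

# method-of-moments NB dispersion on normalized counts.
# Returns list(common, genewise, df) — genewise entries are NA where no
# within-group replication exists.
mom_dispersion <- function(z, group) {
  groups <- split(seq_along(group), group)
  num <- rep(0, nrow(z)); den <- rep(0, nrow(z)); df <- rep(0, nrow(z))
  gw_num <- rep(0, nrow(z)); gw_den <- rep(0, nrow(z))
  for (idx in groups) {
    if (length(idx) < 2L) next
    m <- rowMeans(z[, idx, drop = FALSE])
    v <- apply(z[, idx, drop = FALSE], 1L, stats::var)
    w <- length(idx) - 1L
    ok <- m > 0
    num[ok] <- num[ok] + w * (v[ok] - m[ok])
    den[ok] <- den[ok] + w * m[ok]^2
    df <- df + w
    gw_num[ok] <- gw_num[ok] + w * (v[ok] - m[ok]) / m[ok]^2
    gw_den[ok] <- gw_den[ok] + w
  }
  if (all(den == 0)) return(list(common = NA_real_, genewise = rep(NA_real_, nrow(z)), df = df))
  common <- max(1e-6, sum(num) / sum(den))
  genewise <- ifelse(gw_den > 0, pmax(1e-6, gw_num / gw_den), NA_real_)
  list(common = common, genewise = genewise, df = df)
}

#' Run one caller across all contrasts of a scheme
#'
#' Applies the configured low-count filter, builds the contrast design for the
#' scheme and runs the chosen caller on every contrast, with BH adjustment and
#' up/down/ns calls within each contrast.
#'
#' @param cm a [count_matrix()] covering one tissue
#' @param scheme `"AR"` or `"TC"`
#' @param caller `"exact-nb"`, `"nb-wald"` or `"voom-lm"`
#' @param config a [pipeline_config()]
#' @param stages stage order (default: the matrix's declared stages that are
#'   present for this tissue)
#' @return a `de_table`: data frame with columns `gene`, `contrast`, `lfc`,
#'   `p`, `fdr`, `call`, `caller`, `flag`
#' @export
run_de <- function(cm, scheme = c("AR", "TC"),
                   caller = c("exact-nb", "nb-wald", "voom-lm"),
                   config = pipeline_config(), stages = NULL) {
  scheme <- match.arg(scheme)
  caller <- match.arg(caller)
  cm <- filter_low_counts(cm, config$min_count)
  stages <- stages %||% cm$stages[cm$stages %in% cm$samples$stage]
  design <- build_contrasts(stages, scheme)
  fn <- switch(caller, "exact-nb" = exact_nb_test, "nb-wald" = nb_wald_test,
               "voom-lm" = voom_lm_test)
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    rows <- fn(cm, test = design$test[i], ref = design$ref[i], config = config)
    rows$fdr <- bh_adjust(rows$p)
    rows$call <- call_deg(rows$lfc, rows$fdr, config)
    rows$contrast <- design$label[i]
    rows$caller <- caller
    out[[i]] <- rows[, c("gene", "contrast", "lfc", "p", "fdr", "call", "caller", "flag")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, scheme = scheme, caller = caller, contrasts = design$label,
            class = c("de_table", "data.frame"))
}

#' @export
print.de_table <- function(x, ...) {
  cat(sprintf("de_table (%s, %s scheme): %d genes x %d contrasts\n",
              attr(x, "caller"), attr(x, "scheme"),
              length(unique(x$gene)), length(attr(x, "contrasts"))))
  print(table(contrast = factor(x$contrast, levels = attr(x, "contrasts")),
              call = x$call))
  invisible(x)
}
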