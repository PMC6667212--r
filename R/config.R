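#' Pipeline configuration
#'
#' Central bag of tunable thresholds shared by the DE callers, the jury and
#' the enrichment stage. Defaults follow the conventional "2-fold change and
#' 5% FDR" significance rule.
#'
#' @param lfc_threshold minimum absolute log2 fold change for a DE call
#'   (default 1, i.e. 2-fold).
#' @param fdr_threshold BH-adjusted p cutoff for a DE call (default 0.05).
#' @param enrichment_fdr BH-adjusted p cutoff for an enriched term (default 0.05).
#' @param callers character vector of enabled callers, subset of
#'   `c("exact-nb", "nb-wald", "voom-lm")`.
#' @param schemes contrast schemes to run, subset of `c("AR", "TC")`.
#' @param seed non-negative integer seed used by all stochastic stages.
#' @param min_count low-count filter: a gene is kept if some sample has at
#'   least this many reads (default 1).
#' @param fixed_dispersion NB dispersion used when a contrast has no
#'   replication on either side (default 0.1).
#' @param dispersion_mode `"common"` (one pooled NB dispersion) or `"tagwise"`
#'   (genewise, shrunk toward the pooled value) for the exact NB caller.
#' @param pseudo_count added to normalized group means when forming log2 fold
#'   changes (default 0.5).
#' @param irls_maxit,irls_tol iteration cap and deviance tolerance for the NB
#'   GLM Wald caller.
#' @param lowess_span span of the mean-variance trend smoother in the
#'   voom-style caller.
#' @export
pipeline_config <- function(lfc_threshold = 1,
                            fdr_threshold = 0.05,
                            enrichment_fdr = 0.05,
                            callers = c("exact-nb", "nb-wald", "voom-lm"),
                            schemes = c("AR", "TC"),
                            seed = 1L,
                            min_count = 1L,
                            fixed_dispersion = 0.1,
                            dispersion_mode = c("common", "tagwise"),
                            pseudo_count = 0.5,
                            irls_maxit = 50L,
                            irls_tol = 1e-8,
                            lowess_span = 0.5) {
  dispersion_mode <- match.arg(dispersion_mode)
  cfg <- list(lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold,
              enrichment_fdr = enrichment_fdr, callers = callers,
              schemes = schemes, seed = seed, min_count = min_count,
              fixed_dispersion = fixed_dispersion,
              dispersion_mode = dispersion_mode, pseudo_count = pseudo_count,
              irls_maxit = irls_maxit, irls_tol = irls_tol,
              lowess_span = lowess_span)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$lfc_threshold < 0) stopf("lfc_threshold must be >= 0")
  for (f in c("fdr_threshold", "enrichment_fdr"))
    if (cfg[[f]] <= 0 || cfg[[f]] > 1) stopf("%s must be in (0, 1]", f)
  bad <- setdiff(cfg$callers, c("exact-nb", "nb-wald", "voom-lm"))
  if (length(bad)) stopf("unknown caller: %s", bad[1L])
  bad <- setdiff(cfg$schemes, c("AR", "TC"))
  if (length(bad)) stopf("unknown scheme: %s", bad[1L])
  if (!is.numeric(cfg$seed) || cfg$seed < 0 || cfg$seed != round(cfg$seed))
    stopf("seed must be a non-negative integer")
  if (cfg$min_count < 0) stopf("min_count must be >= 0")
  if (cfg$fixed_dispersion <= 0) stopf("fixed_dispersion must be > 0")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) cat(sprintf("  %-17s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#' @param path YAML file
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config key: %s", bad[1L])
  do.call(pipeline_config, vals)
}

#' Echo a configuration to YAML
#' @param cfg a `pipeline_config`
#' @param path output file
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
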