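#' Published summary counts from a staged water-stress ryegrass study
#'
#' Two small reference tables transcribed from a published RNA-seq study of
#' perennial ryegrass leaf and root tissue sampled at four estimated-water-content
#' stages (35, 15, 5, 1 percent), analysed with three DE callers and the
#' J1/J3 jury scheme. They anchor the bookkeeping and contingency arithmetic
#' of this package to real reported numbers without needing the underlying
#' read data.
#'
#' `ryegrass_deg_counts()` returns the per-contrast DEG counts per analysis
#' method (columns `tissue`, `scheme`, `contrast`, `j1`, `j3`, `deseq2`,
#' `edger`, `limma_voom`).
#'
#' `ryegrass_mirror_counts()` returns the mirror-image enzyme-code contingency
#' inputs and reported Fisher p-values (columns `tissue`, `scheme`,
#' `category1`, `category2`, `n1`, `n2`, `ec`, `description`, `k1`, `k2`,
#' `p_printed`, `upper_bound`); rows with `upper_bound = TRUE` report
#' "p < 1e-4" rather than an exact value.
#'
#' @return a data frame
#' @export
ryegrass_deg_counts <- function() {
  read_tsv(system.file("extdata", "ryegrass_deg_counts.tsv",
                       package = "juryde", mustWork = TRUE))
}

#' @rdname ryegrass_deg_counts
#' @export
ryegrass_mirror_counts <- function() {
  read_tsv(system.file("extdata", "ryegrass_mirror_counts.tsv",
                       package = "juryde", mustWork = TRUE))
}
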