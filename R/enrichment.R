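#' Two-sided Fisher's exact test (probability-mass rule)
#'
#' Exact p-value for a 2x2 contingency table `[a, b; c, d]` by full
#' enumeration of the hypergeometric support with both margins fixed: the
#' two-sided p is the total probability of all tables whose point probability
#' does not exceed that of the observed table. This is the classical
#' two-sided convention of `fisher.test`, reproduced here as an explicit
#' primitive because the mirror-image contingency comparisons quote it
#' directly.
#'
#' @param a,b,c,d non-negative integer cells (first row `a, b`, second `c, d`)
#' @return the two-sided p-value
#' @export
fisher_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stopf("cells must be non-negative integers")
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Propagate annotations up the ontology
#'
#' Closes each gene's GO-term set under ancestors (is_a / part_of). Terms
#' absent from the DAG are kept as-is; namespaces of added terms come from the
#' DAG. Idempotent.
#'
#' @param ann an [annotation_table()]
#' @param dag a [go_dag()]
#' @return a propagated [annotation_table()]
#' @export
propagate_annotations <- function(ann, dag) {
  known <- names(dag$parents)
  anc_cache <- new.env(parent = emptyenv())
  anc <- function(term) {
    if (!term %in% known) return(character())
    got <- anc_cache[[term]]
    if (!is.null(got)) return(got)
    res <- go_ancestors(dag, term)
    assign(term, res, envir = anc_cache)
    res
  }
  genes <- lapply(ann$genes, function(terms)
    sort(unique(c(terms, unlist(lapply(terms, anc), use.names = FALSE)))))
  ns <- ann$namespace
  all_terms <- unique(unlist(genes, use.names = FALSE))
  new_terms <- setdiff(all_terms, names(ns))
  if (length(new_terms)) {
    add <- dag$namespaces[new_terms]
    names(add) <- new_terms
    ns <- c(ns, add[!is.na(add)])
  }
  structure(list(genes = genes, namespace = ns), class = "annotation_table")
}

#' Term enrichment within a trajectory category
#'
#' One two-sided Fisher test per annotated term: category genes against the
#' rest of the annotated universe (the reference set excludes the category,
#' the default two-set contrast; `reference = "whole"` keeps the category
#' inside the reference). P-values are BH-adjusted across the terms tested
#' within the category; records passing the FDR cutoff in the
#' over-represented direction (`k/n > K/N`) are returned, with the category
#' genes carrying the term attached as contributing genes. Depleted terms are
#' available via `direction = "both"`.
#'
#' @param category_genes genes in the category (must be a subset of the universe)
#' @param universe_genes the annotated gene universe
#' @param ann an [annotation_table()] (propagate first if a DAG is in play)
#' @param fdr BH-adjusted cutoff (default 0.05)
#' @param reference `"disjoint"` (universe minus category) or `"whole"`
#' @param direction `"over"` (default) or `"both"`
#' @return data frame of enrichment records: `term`, `namespace`, `k`, `n`,
#'   `K`, `N`, `p`, `padj`, `genes` (semicolon-joined contributing genes)
#' @export
enrich_category <- function(category_genes, universe_genes, ann, fdr = 0.05,
                            reference = c("disjoint", "whole"),
                            direction = c("over", "both")) {
  reference <- match.arg(reference)
  direction <- match.arg(direction)
  if (!all(category_genes %in% universe_genes))
    stopf("category contains gene(s) outside the universe: %s",
          setdiff(category_genes, universe_genes)[1L])
  category_genes <- unique(category_genes)
  universe_genes <- unique(universe_genes)
  n <- length(category_genes); N <- length(universe_genes)
  sets <- ann$genes[intersect(universe_genes, names(ann$genes))]
  term_genes <- split(rep(names(sets), lengths(sets)),
                      unlist(sets, use.names = FALSE))
  if (!length(term_genes))
    return(empty_enrichment())
  terms <- names(term_genes)
  k <- vapply(term_genes, function(g) sum(g %in% category_genes), 1L)
  K <- lengths(term_genes)
  p <- vapply(seq_along(terms), function(i) {
    if (reference == "disjoint")
      fisher_two_sided(k[i], n - k[i], K[i] - k[i], (N - n) - (K[i] - k[i]))
    else
      fisher_two_sided(k[i], n - k[i], K[i], N - n)
  }, 1)
  padj <- bh_adjust(p)
  over <- k / n > K / N
  keep <- padj <= fdr & (over | direction == "both")
  if (!any(keep)) return(empty_enrichment())
  res <- data.frame(term = terms[keep],
                    namespace = unname(ann$namespace[terms[keep]]),
                    k = unname(k[keep]), n = n, K = unname(K[keep]), N = N,
                    p = p[keep], padj = padj[keep],
                    genes = vapply(term_genes[keep], function(g)
                      paste(sort(intersect(g, category_genes)), collapse = ";"), ""),
                    stringsAsFactors = FALSE, row.names = NULL)
  res[order(res$p), , drop = FALSE]
}

empty_enrichment <- function() {
  data.frame(term = character(), namespace = character(), k = integer(),
             n = integer(), K = integer(), N = integer(), p = numeric(),
             padj = numeric(), genes = character(), stringsAsFactors = FALSE)
}

#' Percentage of category genes contributing to at least one enriched term
#'
#' @param category_genes genes in the category
#' @param records enrichment records from [enrich_category()]
#' @return integer percentage (rounded half away from zero); `NA` when no term
#'   is enriched, matching the convention of reporting the cell as absent
#' @export
contributing_percentage <- function(category_genes, records) {
  if (!length(category_genes)) stopf("empty category")
  if (!nrow(records)) return(NA_integer_)
  contributing <- unique(unlist(strsplit(records$genes, ";", fixed = TRUE),
                                use.names = FALSE))
  as.integer(round_half_up(100 * length(intersect(contributing, category_genes)) /
                             length(unique(category_genes))))
}

#' Most-specific enriched terms
#'
#' Keeps the enriched terms having no enriched descendant in the ontology —
#' the "child" terms used when summarising an enrichment by its most specific
#' signal.
#'
#' @param records enrichment records from [enrich_category()]
#' @param dag a [go_dag()]
#' @return the subset of `records` that is most specific
#' @export
most_specific_terms <- function(records, dag) {
  if (!nrow(records)) return(records)
  enriched <- records$term
  keep <- vapply(enriched, function(t) {
    if (!t %in% names(dag$parents)) return(TRUE)
    !any(go_descendants(dag, t) %in% enriched)
  }, TRUE)
  records[keep, , drop = FALSE]
}
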