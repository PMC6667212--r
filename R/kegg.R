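#' Mirror-image enzyme-code contingency comparisons
#'
#' Pairs every trajectory category with its mirror image (up and down swapped
#' at every position) and, for each enzyme code annotated to at least one DEG
#' in either side of a pair, tests whether the code is associated with
#' significantly different numbers of DEGs in the two categories:
#' `p = fisher_two_sided(k1, n1 - k1, k2, n2 - k2)` where `n1`, `n2` are the
#' category sizes and `k1`, `k2` the numbers of category genes carrying the
#' code. Category 1 of a pair is the side whose first non-`ns` token is `up`.
#' Categories whose mirror image is empty are skipped.
#'
#' @param assign a `trajectory_assignment` from [assign_trajectories()]
#' @param ec_ann an [annotation_table()] of enzyme codes
#' @param alpha raw-p screening threshold (default 0.05); rows with `p < alpha`
#'   are returned
#' @param method jury/caller method whose assignment is compared (default `"J1"`)
#' @return data frame `scheme`, `method`, `category1`, `category2`, `n1`, `n2`,
#'   `term`, `k1`, `k2`, `p`
#' @export
mirror_kegg_tests <- function(assign, ec_ann, alpha = 0.05, method = "J1") {
  sub <- assign[assign$method == method, , drop = FALSE]
  if (!nrow(sub)) stopf("method %s absent from the trajectory assignment", method)
  genes_by_cat <- split(sub$gene, sub$category)
  cats <- names(genes_by_cat)
  out <- list()
  for (cat1 in cats) {
    toks <- strsplit(cat1, "_", fixed = TRUE)[[1L]]
    first <- toks[toks != "ns"][1L]
    if (is.na(first) || first != "up") next       # flat, or canonical side is the mirror
    cat2 <- mirror_category(cat1)
    if (!cat2 %in% cats) {
      message(sprintf("category %s has no genes in its mirror image %s; skipped",
                      cat1, cat2))
      next
    }
    g1 <- genes_by_cat[[cat1]]; g2 <- genes_by_cat[[cat2]]
    terms <- sort(unique(unlist(ann_subset_terms(ec_ann, c(g1, g2)), use.names = FALSE)))
    for (term in terms) {
      k1 <- sum(vapply(g1, function(g) term %in% gene_terms(ec_ann, g), TRUE))
      k2 <- sum(vapply(g2, function(g) term %in% gene_terms(ec_ann, g), TRUE))
      if (k1 + k2 == 0L) next
      p <- fisher_two_sided(k1, length(g1) - k1, k2, length(g2) - k2)
      out[[length(out) + 1L]] <- data.frame(
        scheme = sub$scheme[1L], method = method,
        category1 = cat1, category2 = cat2,
        n1 = length(g1), n2 = length(g2),
        term = term, k1 = k1, k2 = k2, p = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(scheme = character(), method = character(),
                      category1 = character(), category2 = character(),
                      n1 = integer(), n2 = integer(), term = character(),
                      k1 = integer(), k2 = integer(), p = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[res$p < alpha, , drop = FALSE]
  rownames(res) <- NULL
  res[order(res$category1, res$p), , drop = FALSE]
}

ann_subset_terms <- function(ann, genes) {
  ann$genes[intersect(unique(genes), names(ann$genes))]
}
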