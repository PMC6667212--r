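#' The expression-trajectory category alphabet
#'
#' Every gene's behaviour over the ordered contrasts of a scheme is summarised
#' as a category string joining one token per contrast, each token one of
#' `up`, `down`, `ns`. Three contrasts give the full 27-category alphabet;
#' two contrasts (the unreplicated-final-stage analysis shape) give 9.
#'
#' @param n_contrasts number of ordered contrasts (default 3)
#' @return character vector of all category strings
#' @export
trajectory_categories <- function(n_contrasts = 3L) {
  tok <- c("up", "down", "ns")
  grids <- rev(expand.grid(rep(list(tok), n_contrasts), stringsAsFactors = FALSE))
  apply(as.matrix(grids), 1L, paste, collapse = "_")
}

#' Classify one gene's ordered calls into a trajectory category
#'
#' @param calls character vector of per-contrast calls in Early-to-Late order,
#'   each `"up"`, `"down"` or `"ns"`.
#' @return the category string, e.g. `"up_down_ns"`
#' @export
classify_trajectory <- function(calls) {
  calls <- as.character(calls)
  bad <- setdiff(calls, c("up", "down", "ns"))
  if (length(bad)) stopf("unknown call label: %s", bad[1L])
  paste(calls, collapse = "_")
}

#' Mirror image of a trajectory category
#'
#' Swaps `up` and `down` at every position; `ns` is fixed. An involution:
#' `mirror_category(mirror_category(x)) == x`.
#' @param category a category string
#' @export
mirror_category <- function(category) {
  tok <- strsplit(category, "_", fixed = TRUE)[[1L]]
  bad <- setdiff(tok, c("up", "down", "ns"))
  if (length(bad)) stopf("invalid category token: %s", bad[1L])
  paste(c(up = "down", down = "up", ns = "ns")[tok], collapse = "_")
}

#' Assign every gene to a trajectory category
#'
#' Pivots a jury table into one category per (gene, method), method being any
#' of the callers or the `J1`/`J3` aggregates, for the scheme the jury table
#' was built under.
#'
#' @param jury a `jury_table` from [jury_aggregate()]
#' @param methods columns of the jury table to classify (default: all callers
#'   plus `J1` and `J3`)
#' @return data frame with columns `gene`, `scheme`, `method`, `category`; the
#'   `ns`-everywhere category is included (callers exclude it from DEG
#'   summaries downstream).
#' @export
assign_trajectories <- function(jury, methods = NULL) {
  methods <- methods %||% attr(jury, "methods")
  labels <- attr(jury, "contrasts")
  genes <- unique(jury$gene)
  out <- vector("list", length(methods))
  for (i in seq_along(methods)) {
    m <- methods[[i]]
    wide <- matrix("ns", nrow = length(genes), ncol = length(labels),
                   dimnames = list(genes, labels))
    wide[cbind(match(jury$gene, genes), match(jury$contrast, labels))] <- jury[[m]]
    out[[i]] <- data.frame(gene = genes, scheme = attr(jury, "scheme"),
                           method = m,
                           category = apply(wide, 1L, paste, collapse = "_"),
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  structure(res, class = c("trajectory_assignment", "data.frame"))
}

#' Tabulate category sizes from a trajectory assignment
#'
#' @param assign a `trajectory_assignment`
#' @param method method to tabulate
#' @param drop_ns drop the all-`ns` category (the non-DEG bucket)?
#' @return data frame `category`, `n`
#' @export
category_sizes <- function(assign, method, drop_ns = TRUE) {
  sub <- assign[assign$method == method, , drop = FALSE]
  tab <- table(sub$category)
  df <- data.frame(category = names(tab), n = as.integer(tab),
                   stringsAsFactors = FALSE)
  if (drop_ns) {
    ns_cat <- paste(rep("ns", length(strsplit(df$category[1L], "_")[[1L]])),
                    collapse = "_")
    df <- df[df$category != ns_cat, , drop = FALSE]
  }
  df[order(df$category), , drop = FALSE]
}
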