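#' Gene Ontology DAG
#'
#' Minimal directed acyclic graph over ontology terms with child-to-parent
#' edges (`is_a` and `relationship: part_of` only — the two relations that
#' enrichment tools conventionally propagate over). Obsolete terms are
#' dropped at parse time.
#'
#' @param parents named list: term id -> character vector of direct parents
#' @param names named character vector of term names
#' @param namespaces named character vector of term namespaces
#' @return object of class `go_dag`
#' @export
go_dag <- function(parents, names = character(), namespaces = character()) {
  parents <- lapply(parents, function(p) unique(p[p %in% base::names(parents)]))
  dag <- structure(list(parents = parents, names = names, namespaces = namespaces,
                        children = invert_edges(parents)),
                   class = "go_dag")
  assert_acyclic(dag)
  dag
}

invert_edges <- function(parents) {
  kids <- list()
  for (child in names(parents)) for (p in parents[[child]])
    kids[[p]] <- c(kids[[p]], child)
  lapply(kids, unique)
}

assert_acyclic <- function(dag) {
  # Kahn's algorithm; leftover nodes imply a cycle
  indeg <- vapply(dag$parents, length, 1L)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in dag$children[[v]] %||% character()) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(dag$parents)) stopf("cyclic is_a/part_of relations in ontology")
  invisible(dag)
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms, %d edges\n", length(x$parents),
              sum(lengths(x$parents))))
  invisible(x)
}

#' All ancestors of a term (transitive closure, term itself excluded)
#' @param dag a `go_dag`
#' @param term term id
#' @export
go_ancestors <- function(dag, term) {
  if (!term %in% names(dag$parents)) stopf("unknown term: %s", term)
  out <- character(); frontier <- dag$parents[[term]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)), out)
  }
  out
}

#' All descendants of a term (transitive closure, term itself excluded)
#' @rdname go_ancestors
#' @export
go_descendants <- function(dag, term) {
  if (!term %in% names(dag$parents)) stopf("unknown term: %s", term)
  out <- character(); frontier <- dag$children[[term]] %||% character()
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(dag$children[frontier], use.names = FALSE)), out)
  }
  out
}

#' Parse an OBO 1.2 ontology file into a DAG
#'
#' Reads `[Term]` stanzas, keeping `id`, `name`, `namespace`, `is_a` and
#' `relationship: part_of` lines. Terms flagged `is_obsolete: true` are
#' dropped, as are edges to terms absent from the file. Cyclic relations are
#' an error.
#'
#' @param path OBO file
#' @return a [go_dag()]
#' @export
read_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  ids <- character(); nms <- character(); nss <- character()
  parents <- list()
  cur <- NULL; cur_parents <- character(); cur_name <- NA_character_
  cur_ns <- NA_character_; cur_obsolete <- FALSE; in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !cur_obsolete) {
      parents[[cur]] <<- unique(cur_parents)
      nms[[cur]] <<- cur_name; nss[[cur]] <<- cur_ns
    }
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)  # strip OBO comments
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); in_term <- TRUE; cur <- NULL
      cur_parents <- character(); cur_name <- NA_character_
      cur_ns <- NA_character_; cur_obsolete <- FALSE; next }
    if (grepl("^\\[", ln)) { flush(); in_term <- FALSE; cur <- NULL; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) {
      cur <- trimws(sub("^id:", "", ln))
      if (!nzchar(cur)) stopf("unreadable stanza: empty id")
    } else if (grepl("^name:", ln)) cur_name <- trimws(sub("^name:", "", ln))
    else if (grepl("^namespace:", ln)) cur_ns <- trimws(sub("^namespace:", "", ln))
    else if (grepl("^is_obsolete:\\s*true", ln)) cur_obsolete <- TRUE
    else if (grepl("^is_a:", ln))
      cur_parents <- c(cur_parents, trimws(sub("^is_a:", "", ln)))
    else if (grepl("^relationship:\\s*part_of\\s", paste0(ln, " ")))
      cur_parents <- c(cur_parents,
                       trimws(sub("^relationship:\\s*part_of\\s+", "", ln)))
  }
  flush()
  if (!length(parents)) stopf("no terms parsed from %s", path)
  go_dag(parents, names = nms, namespaces = nss)
}
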