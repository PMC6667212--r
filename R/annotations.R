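#' Gene-to-term annotation table
#'
#' A mapping from gene id to a set of functional term ids (GO terms or enzyme
#' codes), with an optional namespace per term (BP/MF/CC for GO, "EC" for
#' enzyme codes). Stored as a named list of unique character vectors.
#'
#' @param pairs data frame with columns `gene`, `term` and optionally
#'   `namespace`. Duplicate (gene, term) pairs are collapsed.
#' @return object of class `annotation_table`: list with `genes` (named list of
#'   term sets) and `namespace` (named character vector keyed by term).
#' @export
annotation_table <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L)
    return(structure(list(genes = list(), namespace = character()),
                     class = "annotation_table"))
  pairs$gene <- as.character(pairs$gene)
  pairs$term <- as.character(pairs$term)
  if (any(!nzchar(pairs$term)) || anyNA(pairs$term))
    stopf("empty term token at line %d", which(!nzchar(pairs$term) | is.na(pairs$term))[1L])
  if (any(!nzchar(pairs$gene)) || anyNA(pairs$gene))
    stopf("empty gene token at line %d", which(!nzchar(pairs$gene) | is.na(pairs$gene))[1L])
  genes <- lapply(split(pairs$term, pairs$gene), function(x) sort(unique(x)))
  ns <- character()
  if (!is.null(pairs$namespace)) {
    ns <- tapply(as.character(pairs$namespace), pairs$term, function(x) x[1L])
    ns <- stats::setNames(as.character(ns), names(ns))
  }
  structure(list(genes = genes, namespace = ns), class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("annotation_table: %d genes, %d distinct terms, %d pairs\n",
              length(x$genes), length(unique(unlist(x$genes, use.names = FALSE))),
              n_annotation_pairs(x)))
  invisible(x)
}

#' Total number of (gene, term) pairs in an annotation table
#' @param ann an `annotation_table`
#' @export
n_annotation_pairs <- function(ann) length(unlist(ann$genes, use.names = FALSE))

#' Terms annotated to a gene
#' @param ann an `annotation_table`
#' @param gene gene id
#' @return character vector (empty for unannotated genes)
#' @export
gene_terms <- function(ann, gene) ann$genes[[gene]] %||% character()

#' Read a gene-to-term annotation TSV
#'
#' Accepts either a two-column TSV (`gene`, `term`) where `term` may be a
#' semicolon/comma-delimited list, with an optional third `namespace` column.
#' A header row is detected by the literal column name `gene`.
#'
#' @param path annotation TSV
#' @return an [annotation_table()]
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(annotation_table(data.frame()))
  start <- 1L
  if (grepl("^gene\\t", lines[1L])) start <- 2L
  if (start > length(lines)) return(annotation_table(data.frame()))
  out <- vector("list", length(lines) - start + 1L)
  for (i in seq_along(out)) {
    ln <- i + start - 1L
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) stopf("malformed annotation line %d: expected >= 2 fields", ln)
    terms <- trimws(strsplit(f[2L], "[;,]")[[1L]])
    if (any(!nzchar(terms))) stopf("empty term token at line %d", ln)
    out[[i]] <- data.frame(gene = f[1L], term = terms,
                           namespace = if (length(f) >= 3L) f[3L] else NA_character_,
                           stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out)
  if (all(is.na(pairs$namespace))) pairs$namespace <- NULL
  annotation_table(pairs)
}

#' Write an annotation table as a two/three-column TSV
#' @param ann an `annotation_table`
#' @param path output file
#' @export
write_annotations <- function(ann, path) {
  genes <- rep(names(ann$genes), lengths(ann$genes))
  terms <- unlist(ann$genes, use.names = FALSE)
  df <- data.frame(gene = genes, term = terms, stringsAsFactors = FALSE)
  if (length(ann$namespace)) df$namespace <- unname(ann$namespace[df$term])
  write_tsv(df, path)
}
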