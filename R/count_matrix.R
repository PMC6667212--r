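#' Count matrix with sample metadata
#'
#' Container for a genes x samples matrix of non-negative integer read counts
#' together with the per-sample design metadata of a staged water-stress
#' experiment: tissue, drying stage (an estimated-water-content label from a
#' declared ordered set, wettest first) and replicate number.
#'
#' @param counts integer matrix, genes in rows, samples in columns; rownames
#'   are gene ids, colnames sample ids.
#' @param samples data frame with columns `sample`, `tissue`, `stage`,
#'   `replicate`, one row per column of `counts`, in column order.
#' @param stages character vector declaring stage order from wettest to
#'   driest. Defaults to the distinct stages in `samples` in order of first
#'   appearance. Stage values are design labels: they are never ordered
#'   numerically.
#' @return an object of class `count_matrix`
#' @export
count_matrix <- function(counts, samples, stages = NULL) {
  counts <- as.matrix(counts)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample", "tissue", "stage", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stopf("sample sheet lacks column(s): %s", paste(miss, collapse = ", "))
  samples$sample <- as.character(samples$sample)
  samples$tissue <- as.character(samples$tissue)
  samples$stage <- as.character(samples$stage)
  samples$replicate <- as.integer(samples$replicate)
  stages <- as.character(stages %||% unique(samples$stage))
  obj <- structure(list(counts = counts, samples = samples, stages = stages),
                   class = "count_matrix")
  validate_count_matrix(obj)
}

#' @rdname count_matrix
#' @param x a `count_matrix`
#' @export
validate_count_matrix <- function(x) {
  counts <- x$counts; samples <- x$samples
  if (is.null(rownames(counts))) stopf("counts must have gene ids as rownames")
  if (is.null(colnames(counts))) stopf("counts must have sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate gene id: %s", rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(samples$sample))
    stopf("duplicate sample id: %s", samples$sample[duplicated(samples$sample)][1L])
  if (nrow(samples) != ncol(counts) || !identical(samples$sample, colnames(counts)))
    stopf("sample sheet rows must match count columns in the same order")
  if (!is.numeric(counts) || anyNA(counts))
    stopf("counts must be numeric with no missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stopf("negative count at gene %s, sample %s",
          rownames(counts)[bad[1L]], colnames(counts)[bad[2L]])
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stopf("non-integer count at gene %s, sample %s",
          rownames(counts)[bad[1L]], colnames(counts)[bad[2L]])
  }
  storage.mode(x$counts) <- "double"  # counts kept integral-valued; double avoids overflow
  if (!all(samples$stage %in% x$stages))
    stopf("stage(s) not in the declared stage order: %s",
          paste(setdiff(samples$stage, x$stages), collapse = ", "))
  if (anyNA(samples$replicate) || any(samples$replicate < 1))
    stopf("replicate must be a positive integer for every sample")
  key <- paste(samples$tissue, samples$stage, samples$replicate)
  if (anyDuplicated(key))
    stopf("duplicated (tissue, stage, replicate): %s", key[duplicated(key)][1L])
  x
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  tab <- table(tissue = x$samples$tissue,
                stage = factor(x$samples$stage, levels = x$stages))
  print(tab)
  invisible(x)
}

#' Number of genes / samples in a count matrix
#' @param cm a `count_matrix`
#' @export
n_genes <- function(cm) nrow(cm$counts)

#' @rdname n_genes
#' @export
n_samples <- function(cm) ncol(cm$counts)

#' Subset a count matrix by sample
#' @param cm a `count_matrix`
#' @param keep logical or index vector over samples
#' @export
subset_samples <- function(cm, keep) {
  count_matrix(cm$counts[, keep, drop = FALSE], cm$samples[keep, , drop = FALSE],
               stages = cm$stages)
}

#' Read a count matrix and its sample sheet
#'
#' The counts file is a TSV whose header row holds sample ids and whose first
#' column holds gene ids; the sample sheet is a TSV with columns `sample`,
#' `tissue`, `stage`, `replicate`. Sample order follows the sheet. Any sample
#' present in only one of the two files is an error naming that sample.
#'
#' @param counts_path path to the counts TSV
#' @param sheet_path path to the sample-sheet TSV
#' @param stages optional declared stage order (wettest first)
#' @return a [count_matrix()]
#' @export
read_counts <- function(counts_path, sheet_path, stages = NULL) {
  raw <- utils::read.delim(counts_path, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stopf("counts file %s has no sample columns", counts_path)
  genes <- raw[[1L]]
  if (anyDuplicated(genes)) stopf("duplicate gene id: %s", genes[duplicated(genes)][1L])
  sheet <- utils::read.delim(sheet_path, sep = "\t", quote = "",
                             stringsAsFactors = FALSE)
  sheet$sample <- as.character(sheet$sample)
  missing_in_counts <- setdiff(sheet$sample, names(raw)[-1L])
  if (length(missing_in_counts))
    stopf("sample '%s' in sample sheet but not in counts header", missing_in_counts[1L])
  missing_in_sheet <- setdiff(names(raw)[-1L], sheet$sample)
  if (length(missing_in_sheet))
    stopf("sample '%s' in counts header but not in sample sheet", missing_in_sheet[1L])
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = nrow(sheet),
                dimnames = list(genes, sheet$sample))
  for (s in sheet$sample) {
    v <- suppressWarnings(as.numeric(raw[[s]]))
    if (anyNA(v))
      stopf("non-numeric count at row %d, sample %s", which(is.na(v))[1L], s)
    mat[, s] <- v
  }
  count_matrix(mat, sheet, stages = stages)
}

#' Write a count matrix and sample sheet as TSV
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(cm, ...))` returns an
#' identical object.
#' @param cm a `count_matrix`
#' @param counts_path,sheet_path output paths
#' @export
write_counts <- function(cm, counts_path, sheet_path) {
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(cm$samples, sheet_path)
  invisible(c(counts = counts_path, sheet = sheet_path))
}
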