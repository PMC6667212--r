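# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed` so seeded simulation helpers
#' never perturb the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stopf("seed must be a single non-negative integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# round-half-away-from-zero, used for all displayed integer percentages
# (base round() is round-half-to-even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

geometric_mean <- function(x) exp(mean(log(x)))

#' Write a data frame as TSV
#'
#' Fixed dialect used for every result table: tab-separated, no quoting,
#' UTF-8, numeric columns at full precision.
#' @param x data frame
#' @param path output file
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input file
#' @param ... passed to [utils::read.delim()]
#' @export
read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}
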