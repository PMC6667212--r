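#' Aggregate per-caller DE calls into jury verdicts
#'
#' Combines the result tables of the individual callers into the two jury
#' classes: `J1` (union — significant by any caller) and `J3` (intersection —
#' significant by all callers). J1 takes the direction of the calling
#' caller(s); if two callers disagree on direction for the same gene and
#' contrast the J1 call is set to `ns` and the conflict flagged. J3 is `up`
#' (`down`) only when every caller calls `up` (`down`).
#'
#' @param tables list of `de_table` objects from [run_de()], one per caller,
#'   covering identical genes, contrasts and scheme
#' @return a `jury_table`: data frame with columns `gene`, `contrast`, one
#'   call column per caller, `J1`, `J3`, `conflict`
#' @export
jury_aggregate <- function(tables) {
  if (length(tables) < 1L) stopf("need at least one caller table")
  callers <- vapply(tables, function(t) attr(t, "caller"), "")
  if (anyDuplicated(callers)) stopf("duplicate caller table: %s", callers[duplicated(callers)][1L])
  schemes <- unique(vapply(tables, function(t) attr(t, "scheme"), ""))
  if (length(schemes) != 1L) stopf("caller tables mix schemes: %s", paste(schemes, collapse = ", "))
  key0 <- paste(tables[[1L]]$gene, tables[[1L]]$contrast)
  base <- tables[[1L]][order(key0), c("gene", "contrast")]
  out <- base
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    key <- paste(t$gene, t$contrast)
    missing <- setdiff(key0, key)
    extra <- setdiff(key, key0)
    if (length(missing) || length(extra))
      stopf("caller %s covers different genes/contrasts (e.g. %s)",
            callers[i], c(extra, missing)[1L])
    out[[callers[i]]] <- t$call[order(key)]
  }
  calls <- as.matrix(out[, callers, drop = FALSE])
  any_up <- rowSums(calls == "up") > 0
  any_dn <- rowSums(calls == "down") > 0
  all_up <- rowSums(calls == "up") == length(callers)
  all_dn <- rowSums(calls == "down") == length(callers)
  out$J1 <- ifelse(any_up & !any_dn, "up", ifelse(any_dn & !any_up, "down", "ns"))
  out$J3 <- ifelse(all_up, "up", ifelse(all_dn, "down", "ns"))
  out$conflict <- any_up & any_dn
  rownames(out) <- NULL
  structure(out, scheme = schemes, callers = callers,
            methods = c(callers, "J1", "J3"),
            contrasts = attr(tables[[1L]], "contrasts"),
            class = c("jury_table", "data.frame"))
}

#' @export
print.jury_table <- function(x, ...) {
  cat(sprintf("jury_table (%s scheme; callers %s)\n", attr(x, "scheme"),
              paste(attr(x, "callers"), collapse = ", ")))
  for (m in c("J1", "J3"))
    cat(sprintf("  %s significant: %d of %d (gene, contrast) pairs\n",
                m, sum(x[[m]] != "ns"), nrow(x)))
  if (any(x$conflict))
    cat(sprintf("  %d direction conflict(s) resolved to ns\n", sum(x$conflict)))
  invisible(x)
}

#' Partition the J1 set by caller combination
#'
#' For one contrast, partitions the J1-significant genes into the seven
#' possible non-empty combinations of calling callers and reports each cell as
#' an integer percentage of J1 (rounded half away from zero).
#'
#' @param jury a `jury_table`
#' @param contrast contrast label
#' @return data frame `combination`, `n`, `pct`; attribute `j1` holds |J1|
#' @export
combination_table <- function(jury, contrast) {
  callers <- attr(jury, "callers")
  sub <- jury[jury$contrast == contrast, , drop = FALSE]
  if (!nrow(sub)) stopf("contrast %s absent from the jury table", contrast)
  in_j1 <- sub$J1 != "ns" | sub$conflict   # any caller significant
  combos <- unlist(lapply(rev(seq_along(callers)), function(k)
    utils::combn(callers, k, paste, collapse = ",", simplify = FALSE)),
    use.names = FALSE)
  sig <- as.matrix(sub[, callers, drop = FALSE]) != "ns"
  membership <- apply(sig[in_j1, , drop = FALSE], 1L, function(row)
    paste(callers[row], collapse = ","))
  n_j1 <- sum(in_j1)
  n <- vapply(combos, function(cb) sum(membership == cb), 1L)
  pct <- if (n_j1 > 0) round_half_up(100 * n / n_j1) else rep(0, length(n))
  structure(data.frame(combination = combos, n = n, pct = pct,
                       stringsAsFactors = FALSE),
            j1 = n_j1, class = c("combination_table", "data.frame"))
}

#' Minimum J3/J1 percentage across contrasts
#'
#' The headline jury-concordance figure: for each contrast the J3 set size as
#' an integer percentage of the J1 set size, minimized over contrasts.
#' Accepts either a `jury_table` (or list of them) or two vectors of J1 and J3
#' set sizes.
#'
#' @param x a `jury_table`, a list of `jury_table`s, or a numeric vector of J1
#'   set sizes
#' @param j3 numeric vector of J3 set sizes when `x` is numeric
#' @return integer percentage
#' @export
min_j3_percentage <- function(x, j3 = NULL) {
  if (is.numeric(x)) {
    j1 <- x
    if (is.null(j3) || length(j3) != length(j1)) stopf("need matching J1 and J3 counts")
  } else {
    tabs <- if (inherits(x, "jury_table")) list(x) else x
    j1 <- j3v <- numeric()
    for (t in tabs) for (ct in attr(t, "contrasts")) {
      sub <- t[t$contrast == ct, , drop = FALSE]
      j1 <- c(j1, sum(sub$J1 != "ns" | sub$conflict))
      j3v <- c(j3v, sum(sub$J3 != "ns"))
    }
    j3 <- j3v
  }
  keep <- j1 > 0
  if (!any(keep)) stopf("all contrasts have an empty J1 set")
  as.integer(min(round_half_up(100 * j3[keep] / j1[keep])))
}
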