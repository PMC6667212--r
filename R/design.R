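#' Build the contrast design for a staged experiment
#'
#' From an ordered set of drying stages (wettest first) derives the ordered
#' contrasts of one of two schemes: against-reference (`AR`), where every
#' later stage is compared to the first, fully watered stage; or time-course
#' (`TC`), where each stage is compared to the immediately preceding stage.
#' With k stages there are k - 1 contrasts, labelled `Early`, `Middle`,
#' `Late` (then `Stage5`, ... for longer series).
#'
#' @param stages ordered character/numeric vector of stage labels, wettest
#'   first (default `c("35", "15", "5", "1")`, estimated-water-content
#'   percentages).
#' @param scheme `"AR"` or `"TC"`.
#' @return object of class `stage_design`: data frame with columns `label`,
#'   `test`, `ref` plus attributes `scheme` and `stages`.
#' @export
build_contrasts <- function(stages = c("35", "15", "5", "1"),
                            scheme = c("AR", "TC")) {
  scheme <- match.arg(scheme)
  stages <- as.character(stages)
  if (length(stages) < 2L) stopf("need at least 2 stages to form a contrast")
  if (anyDuplicated(stages)) stopf("duplicated stage label")
  k <- length(stages) - 1L
  labels <- c("Early", "Middle", "Late", paste0("Stage", seq_len(max(0L, k - 3L)) + 4L))[seq_len(k)]
  ref <- if (scheme == "AR") rep(stages[1L], k) else stages[seq_len(k)]
  design <- data.frame(label = labels, test = stages[-1L], ref = ref,
                       stringsAsFactors = FALSE)
  structure(design, scheme = scheme, stages = stages,
            class = c("stage_design", "data.frame"))
}

#' @export
print.stage_design <- function(x, ...) {
  cat(sprintf("stage_design (%s scheme, stages %s):\n", attr(x, "scheme"),
              paste(attr(x, "stages"), collapse = " > ")))
  print(as.data.frame(x))
  invisible(x)
}
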