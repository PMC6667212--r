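#' Simulate a staged negative-binomial count matrix with designed trajectories
#'
#' Emulates the design of a staged drying experiment: one tissue, an ordered
#' set of drying stages sampled in quadruplicate, negative-binomial counts
#' with variance mu + dispersion * mu^2, log-normal library-size variation and
#' per-gene expression trajectories drawn from the 27-way category alphabet.
#' A gene's designed log2 fold change at each against-reference (AR) contrast
#' is `+effect_size`, `-effect_size` or 0 according to its category token; the
#' stage mean is `baseline * 2^(designed AR lfc at that stage) * library
#' factor`. Time-course (TC) truth is derived by differencing the cumulative
#' AR log2 means, so a single truth table serves both schemes.
#'
#' @param n_genes number of genes
#' @param stages ordered stage labels, wettest first
#' @param replicates replicates per stage (scalar or vector along `stages`)
#' @param category_weights named numeric vector of probabilities over the
#'   category alphabet (names are category strings; must sum to 1). Default:
#'   65% of genes flat (`ns` everywhere), the rest spread evenly.
#' @param effect_size designed |log2 fold change| of non-`ns` tokens
#' @param dispersion NB dispersion, scalar or per-gene vector
#' @param libsize_cv coefficient of variation of log-normal per-sample
#'   library-size factors (mean 1)
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of per-gene
#'   baseline means
#' @param tissue tissue label for the sample sheet
#' @param lfc_threshold threshold used to translate designed fold changes back
#'   into designed category tokens (so `effect_size = 0` designs are recorded
#'   as flat)
#' @param seed RNG seed; identical seeds give identical output
#' @return list with `counts` (a [count_matrix()]) and `truth` (data frame:
#'   gene, baseline, dispersion, one `lfc_<label>` column per AR contrast,
#'   `category_ar`, `category_tc`; attribute `lib_factors` holds the
#'   per-sample factors)
#' @export
simulate_counts <- function(n_genes,
                            stages = c("35", "15", "5", "1"),
                            replicates = 4L,
                            category_weights = NULL,
                            effect_size = 2,
                            dispersion = 0.05,
                            libsize_cv = 0.3,
                            baseline_meanlog = log(100),
                            baseline_sdlog = 1,
                            tissue = "leaf",
                            lfc_threshold = 1,
                            seed = 1L) {
  design <- build_contrasts(stages, "AR")
  k <- nrow(design)
  cats <- trajectory_categories(k)
  if (is.null(category_weights)) {
    flat <- paste(rep("ns", k), collapse = "_")
    category_weights <- stats::setNames(rep(0.35 / (length(cats) - 1L), length(cats)), cats)
    category_weights[flat] <- 0.65
  }
  if (!all(names(category_weights) %in% cats) || is.null(names(category_weights)))
    stopf("category_weights names must be category strings over %d contrasts", k)
  if (abs(sum(category_weights) - 1) > 1e-6)
    stopf("category_weights must sum to 1 (got %.6f)", sum(category_weights))
  if (effect_size < 0) stopf("effect_size must be >= 0")
  replicates <- rep(as.integer(replicates), length.out = length(stages))
  if (any(replicates < 1)) stopf("need at least 1 replicate per stage (incl. the reference)")
  dispersion <- rep(dispersion, length.out = n_genes)
  if (any(dispersion <= 0)) stopf("dispersion must be > 0")

  with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    baseline <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    target <- sample(names(category_weights), n_genes, replace = TRUE,
                     prob = category_weights)
    toks <- do.call(rbind, strsplit(target, "_", fixed = TRUE))
    sgn <- matrix(0, n_genes, k)
    sgn[toks == "up"] <- 1; sgn[toks == "down"] <- -1
    lfc_ar <- sgn * effect_size                       # genes x contrasts, log2

    sheet <- do.call(rbind, lapply(seq_along(stages), function(i)
      data.frame(sample = sprintf("%s_s%s_r%d", tissue, stages[i], seq_len(replicates[i])),
                 tissue = tissue, stage = stages[i], replicate = seq_len(replicates[i]),
                 stringsAsFactors = FALSE)))
    sdlog <- sqrt(log(1 + libsize_cv^2))
    lib <- stats::rlnorm(nrow(sheet), -sdlog^2 / 2, sdlog)   # mean 1
    names(lib) <- sheet$sample

    cum_lfc <- cbind(0, lfc_ar)[, match(sheet$stage, stages), drop = FALSE]
    mu <- baseline * 2^cum_lfc * rep(lib, each = n_genes)
    counts <- matrix(stats::rnbinom(length(mu), size = rep(1 / dispersion, ncol(mu)),
                                    mu = mu),
                     nrow = n_genes, dimnames = list(genes, sheet$sample))

    tok_of <- function(x) ifelse(x >= lfc_threshold, "up",
                          ifelse(x <= -lfc_threshold, "down", "ns"))
    cat_ar <- apply(matrix(tok_of(lfc_ar), n_genes), 1L, paste, collapse = "_")
    lfc_tc <- lfc_ar - cbind(0, lfc_ar[, -k, drop = FALSE])
    cat_tc <- apply(matrix(tok_of(lfc_tc), n_genes), 1L, paste, collapse = "_")

    truth <- data.frame(gene = genes, baseline = baseline, dispersion = dispersion,
                        stringsAsFactors = FALSE)
    for (j in seq_len(k)) truth[[paste0("lfc_", design$label[j])]] <- lfc_ar[, j]
    truth$category_ar <- cat_ar
    truth$category_tc <- cat_tc
    attr(truth, "lib_factors") <- data.frame(sample = sheet$sample, factor = unname(lib),
                                             stringsAsFactors = FALSE)
    list(counts = count_matrix(counts, sheet, stages = stages), truth = truth)
  })
}

#' Simulate gene annotations with planted term enrichment
#'
#' Background terms are assigned to every gene independently at a fixed
#' prevalence. Each planted term is assigned with elevated probability inside
#' its target trajectory category so that the expected 2x2 odds ratio against
#' the rest of the gene universe equals the requested odds (infinite odds put
#' the term only inside the category).
#'
#' @param truth truth table from [simulate_counts()]
#' @param n_terms number of background terms
#' @param planted list of `list(term =, category =, odds =, scheme =)` entries;
#'   `scheme` is `"ar"` (default) or `"tc"` and selects which designed category
#'   column is targeted.
#' @param base_prevalence background annotation probability per (gene, term)
#' @param namespace namespace recorded for every term
#' @param seed RNG seed
#' @return an [annotation_table()]
#' @export
simulate_annotations <- function(truth, n_terms = 50L, planted = list(),
                                 base_prevalence = 0.1, namespace = "BP",
                                 seed = 1L) {
  planted_terms <- vapply(planted, `[[`, "", "term")
  if (anyDuplicated(planted_terms))
    stopf("planted term duplicated: %s", planted_terms[duplicated(planted_terms)][1L])
  genes <- truth$gene
  with_seed(seed, {
    rows <- list()
    if (n_terms > 0L) {
      bg <- sprintf("T%04d", seq_len(n_terms))
      hit <- matrix(stats::runif(length(genes) * n_terms) < base_prevalence,
                    nrow = length(genes))
      idx <- which(hit, arr.ind = TRUE)
      if (nrow(idx)) rows[[1L]] <- data.frame(gene = genes[idx[, 1L]],
                                              term = bg[idx[, 2L]],
                                              stringsAsFactors = FALSE)
    }
    for (p in planted) {
      odds <- p$odds
      if (is.null(odds) || odds < 1) stopf("planted odds must be >= 1")
      col <- if (identical(p$scheme %||% "ar", "tc")) "category_tc" else "category_ar"
      inside <- truth[[col]] == p$category
      if (!any(inside)) stopf("target category %s absent from the truth table", p$category)
      if (is.infinite(odds)) { p0 <- 0; p1 <- 0.5 }
      else { p0 <- base_prevalence; p1 <- odds * p0 / (1 - p0 + odds * p0) }
      pr <- ifelse(inside, p1, p0)
      hit <- stats::runif(length(genes)) < pr
      if (any(hit)) rows[[length(rows) + 1L]] <-
          data.frame(gene = genes[hit], term = p$term, stringsAsFactors = FALSE)
    }
    if (!length(rows)) return(annotation_table(data.frame()))
    pairs <- do.call(rbind, rows)
    pairs$namespace <- namespace
    annotation_table(pairs)
  })
}

#' Drop replicates at one stage
#'
#' Emulates replicate loss (e.g. an unreplicated final drying stage) by
#' retaining a random subset of `keep` replicates at the given stage and
#' leaving every other sample untouched.
#'
#' @param cm a [count_matrix()]
#' @param stage stage label whose replicates are thinned
#' @param keep number of replicates to retain (>= 1)
#' @param seed RNG seed (same seed retains the same samples)
#' @param tissue optional tissue restriction
#' @export
drop_replicates <- function(cm, stage, keep, seed = 1L, tissue = NULL) {
  stage <- as.character(stage)
  at <- cm$samples$stage == stage &
    (if (is.null(tissue)) TRUE else cm$samples$tissue == tissue)
  if (!any(at)) stopf("stage %s absent from the count matrix", stage)
  n_at <- sum(at)
  if (keep < 1 || keep > n_at)
    stopf("keep must be in [1, %d] for stage %s", n_at, stage)
  if (keep == n_at) return(cm)
  retained <- with_seed(seed, sample(which(at), keep))
  subset_samples(cm, sort(c(which(!at), retained)))
}
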