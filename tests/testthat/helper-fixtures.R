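# Fixtures are built in code: small count matrices, toy ontologies and
# hand-made caller tables used across the suite.

make_cm <- function(counts, stages, tissue = "leaf") {
  reps <- as.integer(ave(seq_along(stages), stages, FUN = seq_along))
  colnames(counts) <- sprintf("%s_s%s_r%d", tissue, stages, reps)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  sheet <- data.frame(sample = colnames(counts), tissue = tissue,
                      stage = stages, replicate = reps,
                      stringsAsFactors = FALSE)
  count_matrix(counts, sheet, stages = unique(stages))
}

# a two-stage matrix with given per-group means, NB noise
two_group_cm <- function(n_genes, n_per_group, mu_ref, mu_test,
                         dispersion = 0.05, seed = 1) {
  set.seed(seed)
  mu <- cbind(matrix(mu_ref, n_genes, n_per_group),
              matrix(mu_test, n_genes, n_per_group))
  counts <- matrix(rnbinom(length(mu), size = 1 / dispersion, mu = mu),
                   nrow = n_genes)
  make_cm(counts, stages = rep(c("35", "15"), each = n_per_group))
}

# fabricate a de_table carrying given calls (one row per gene x contrast)
fake_de_table <- function(genes, contrasts, calls, caller, scheme = "AR") {
  stopifnot(is.matrix(calls), nrow(calls) == length(genes),
            ncol(calls) == length(contrasts))
  df <- do.call(rbind, lapply(seq_along(contrasts), function(j)
    data.frame(gene = genes, contrast = contrasts[j],
               lfc = ifelse(calls[, j] == "up", 2,
                            ifelse(calls[, j] == "down", -2, 0)),
               p = ifelse(calls[, j] == "ns", 0.5, 1e-4),
               fdr = ifelse(calls[, j] == "ns", 0.8, 1e-3),
               call = calls[, j], caller = caller, flag = "",
               stringsAsFactors = FALSE)))
  structure(df, scheme = scheme, caller = caller, contrasts = contrasts,
            class = c("de_table", "data.frame"))
}

random_call_matrix <- function(n_genes, n_contrasts, seed) {
  set.seed(seed)
  matrix(sample(c("up", "down", "ns"), n_genes * n_contrasts, replace = TRUE,
                prob = c(0.2, 0.2, 0.6)),
         nrow = n_genes)
}

write_toy_obo <- function(path, chain = c("GO:0000003", "GO:0000002", "GO:0000001"),
                          extra = "") {
  stanzas <- c("format-version: 1.2", "")
  for (i in seq_along(chain)) {
    stanzas <- c(stanzas, "[Term]", paste0("id: ", chain[i]),
                 paste0("name: term", i), "namespace: biological_process")
    if (i < length(chain))
      stanzas <- c(stanzas, paste0("is_a: ", chain[i + 1L], " ! parent"))
    stanzas <- c(stanzas, "")
  }
  writeLines(c(stanzas, extra), path)
  path
}

# random DAG over n terms: edges only from higher to lower index
random_dag_parents <- function(n, p_edge = 0.3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(n))
  parents <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    if (i == 1L) { parents[[i]] <- character(); next }
    cand <- ids[seq_len(i - 1L)]
    parents[[i]] <- cand[runif(length(cand)) < p_edge]
  }
  parents
}

# brute-force reachability for the DAG oracle
brute_force_ancestors <- function(parents, term) {
  ids <- names(parents)
  adj <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (ch in ids) adj[ch, parents[[ch]]] <- TRUE
  reach <- adj
  for (i in seq_along(ids)) reach <- reach | (reach %*% adj > 0)
  ids[reach[term, ]]
}
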