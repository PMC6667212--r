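test_that("fisher_two_sided is exact on printed and degenerate tables", {
  expect_equal(fisher_two_sided(5, 100, 1, 165), 3.39e-2, tolerance = 5e-3)
  expect_equal(fisher_two_sided(1, 1, 1, 1), 1)
  expect_equal(fisher_two_sided(0, 0, 0, 0), 1)
  expect_error(fisher_two_sided(-1, 2, 3, 4), "non-negative")
})

test_that("fisher_two_sided equals full enumeration for all margins <= 60", {
  # independent oracle: binomial coefficients, no dhyper
  enum_p <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    supp <- max(0, k - n):min(k, m)
    pr <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
    obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
    sum(pr[pr <= obs * (1 + 1e-7)])
  }
  set.seed(14)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(4:60, 1), runif(4, 0.05, 1)))
    p <- fisher_two_sided(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p, enum_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
    expect_equal(p, fisher.test(matrix(cells, 2))$p.value, tolerance = 1e-9)
  }
})

test_that("fisher_two_sided is symmetric under row and column swaps", {
  set.seed(15)
  for (i in 1:50) {
    cl <- as.integer(sample(0:40, 4, replace = TRUE))
    p <- fisher_two_sided(cl[1], cl[2], cl[3], cl[4])
    expect_equal(p, fisher_two_sided(cl[3], cl[4], cl[1], cl[2]), tolerance = 1e-12)
    expect_equal(p, fisher_two_sided(cl[2], cl[1], cl[4], cl[3]), tolerance = 1e-12)
  }
})

test_that("annotation propagation closes over ancestors and is idempotent", {
  p <- withr::local_tempfile(fileext = ".obo")
  write_toy_obo(p)  # GO:0000003 is_a GO:0000002 is_a GO:0000001
  dag <- read_obo(p)
  ann <- annotation_table(data.frame(gene = c("g1", "g2"),
                                     term = c("GO:0000003", "GO:0000001")))
  prop <- propagate_annotations(ann, dag)
  expect_setequal(gene_terms(prop, "g1"),
                  c("GO:0000003", "GO:0000002", "GO:0000001"))
  expect_identical(gene_terms(prop, "g2"), "GO:0000001")  # root-only unchanged
  expect_identical(propagate_annotations(prop, dag)$genes, prop$genes)
})

test_that("enrichment finds a planted all-or-nothing term and agrees with the primitive", {
  sim <- simulate_counts(500, effect_size = 2, seed = 10)
  ann <- simulate_annotations(sim$truth, n_terms = 20,
                              planted = list(list(term = "GO:PLANT",
                                                  category = "ns_ns_down",
                                                  odds = Inf)),
                              seed = 3)
  universe <- sim$truth$gene
  cat_genes <- sim$truth$gene[sim$truth$category_ar == "ns_ns_down"]
  rec <- enrich_category(cat_genes, universe, ann, fdr = 0.05)
  expect_true("GO:PLANT" %in% rec$term)
  for (i in seq_len(nrow(rec))) {
    expect_equal(rec$p[i],
                 fisher_two_sided(rec$k[i], rec$n[i] - rec$k[i],
                                  rec$K[i] - rec$k[i],
                                  (rec$N[i] - rec$n[i]) - (rec$K[i] - rec$k[i])),
                 tolerance = 1e-12)
    expect_gte(rec$padj[i], rec$p[i])
    expect_true(rec$k[i] <= min(rec$n[i], rec$K[i]))
  }
  row <- rec[rec$term == "GO:PLANT", ]
  contrib <- strsplit(row$genes, ";")[[1]]
  expect_true(all(contrib %in% cat_genes))
  expect_identical(length(contrib), row$k)
  # category == universe has no contrast left
  expect_identical(nrow(enrich_category(universe, universe, ann)), 0L)
  expect_error(enrich_category(c(cat_genes, "nope"), universe, ann), "outside")
})

test_that("enrichment p-values are invariant to gene relabelling", {
  sim <- simulate_counts(200, effect_size = 2, seed = 44)
  ann <- simulate_annotations(sim$truth, n_terms = 10, seed = 5)
  universe <- sim$truth$gene
  cat_genes <- sim$truth$gene[sim$truth$category_ar != "ns_ns_ns"][1:40]
  rec1 <- enrich_category(cat_genes, universe, ann, fdr = 1)
  relabel <- setNames(sprintf("x%04d", seq_along(universe)), universe)
  ann2 <- ann
  names(ann2$genes) <- unname(relabel[names(ann$genes)])
  rec2 <- enrich_category(unname(relabel[cat_genes]), unname(relabel), ann2, fdr = 1)
  expect_equal(sort(rec1$p), sort(rec2$p), tolerance = 1e-12)
})

test_that("null-planted annotations rarely produce false enrichment", {
  # with no planted terms BH controls the per-category any-false-positive rate
  sim <- simulate_counts(300, effect_size = 2, seed = 50)
  universe <- sim$truth$gene
  cats <- split(sim$truth$gene, sim$truth$category_ar)
  cats <- cats[names(cats) != "ns_ns_ns" & lengths(cats) >= 5]
  hits <- 0L; trials <- 0L
  for (rep_seed in 1:8) {
    ann <- simulate_annotations(sim$truth, n_terms = 25, seed = 100 + rep_seed)
    for (cg in cats) {
      trials <- trials + 1L
      hits <- hits + (nrow(enrich_category(cg, universe, ann, fdr = 0.05)) > 0L)
    }
  }
  rate <- hits / trials
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / trials))
})

test_that("contributing percentage equals a brute-force union count", {
  sim <- simulate_counts(600, effect_size = 2, seed = 60)
  ann <- simulate_annotations(sim$truth, n_terms = 15,
                              planted = list(list(term = "GO:X",
                                                  category = "ns_ns_up",
                                                  odds = Inf)), seed = 7)
  universe <- sim$truth$gene
  cat_genes <- sim$truth$gene[sim$truth$category_ar == "ns_ns_up"]
  rec <- enrich_category(cat_genes, universe, ann, fdr = 0.05)
  pct <- contributing_percentage(cat_genes, rec)
  union_genes <- unique(unlist(strsplit(rec$genes, ";")))
  expect_identical(pct,
                   as.integer(floor(100 * length(intersect(union_genes, cat_genes)) /
                                      length(cat_genes) + 0.5)))
  expect_identical(contributing_percentage(cat_genes, rec[0, ]), NA_integer_)
  expect_error(contributing_percentage(character(), rec), "empty category")
  # all category genes carrying a single enriched term give 100
  ann_all <- annotation_table(data.frame(gene = universe,
                                         term = ifelse(universe %in% cat_genes,
                                                       "GO:ALL", "GO:OTHER")))
  rec_all <- enrich_category(cat_genes, universe, ann_all, fdr = 0.05)
  expect_identical(contributing_percentage(cat_genes, rec_all), 100L)
})

test_that("most-specific filtering keeps terms with no enriched descendant", {
  p <- withr::local_tempfile(fileext = ".obo")
  write_toy_obo(p, extra = paste(
    "[Term]", "id: GO:0000005", "name: sib", "is_a: GO:0000002", "", sep = "\n"))
  dag <- read_obo(p)
  rec <- data.frame(term = c("GO:0000001", "GO:0000002", "GO:0000003"),
                    stringsAsFactors = FALSE)
  expect_identical(most_specific_terms(rec, dag)$term, "GO:0000003")
  sib <- data.frame(term = c("GO:0000003", "GO:0000005"), stringsAsFactors = FALSE)
  expect_identical(most_specific_terms(sib, dag)$term, c("GO:0000003", "GO:0000005"))
  # brute-force oracle on a random DAG
  parents <- random_dag_parents(10, p_edge = 0.3, seed = 2)
  rdag <- go_dag(parents)
  enr <- data.frame(term = sample(names(parents), 6), stringsAsFactors = FALSE)
  keep_oracle <- sapply(enr$term, function(t) {
    desc <- character()
    frontier <- t
    repeat {
      kids <- names(parents)[sapply(parents, function(p) any(frontier %in% p))]
      kids <- setdiff(kids, c(desc, t))
      if (!length(kids)) break
      desc <- c(desc, kids); frontier <- kids
    }
    !any(desc %in% enr$term)
  })
  expect_identical(most_specific_terms(enr, rdag)$term, enr$term[keep_oracle])
})
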