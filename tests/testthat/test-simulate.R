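test_that("identical seeds give byte-identical output, different seeds differ", {
  a <- simulate_counts(50, seed = 11)
  b <- simulate_counts(50, seed = 11)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  pa <- withr::local_tempfile(); pb <- withr::local_tempfile()
  sa <- withr::local_tempfile(); sb <- withr::local_tempfile()
  write_counts(a$counts, pa, sa); write_counts(b$counts, pb, sb)
  expect_identical(readLines(pa), readLines(pb))
  c <- simulate_counts(50, seed = 12)
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("a zero effect size designs every gene as flat", {
  sim <- simulate_counts(80, effect_size = 0, seed = 4)
  expect_true(all(sim$truth$category_ar == "ns_ns_ns"))
  expect_true(all(sim$truth$category_tc == "ns_ns_ns"))
  expect_true(all(sim$truth[, grep("^lfc_", names(sim$truth))] == 0))
})

test_that("designed categories are consistent with designed fold changes", {
  sim <- simulate_counts(300, effect_size = 2, seed = 8)
  lfc <- as.matrix(sim$truth[, c("lfc_Early", "lfc_Middle", "lfc_Late")])
  tok <- ifelse(lfc >= 1, "up", ifelse(lfc <= -1, "down", "ns"))
  expect_identical(apply(tok, 1, paste, collapse = "_"), sim$truth$category_ar)
  # TC truth is the difference of cumulative AR truth
  tc <- lfc - cbind(0, lfc[, -3])
  tok_tc <- ifelse(tc >= 1, "up", ifelse(tc <= -1, "down", "ns"))
  expect_identical(apply(tok_tc, 1, paste, collapse = "_"), sim$truth$category_tc)
})

test_that("simulated moments match the NB mean-variance law", {
  # two stages, many replicates, no library noise: var ~ mu + alpha mu^2
  sim <- simulate_counts(6, stages = c("35", "15"), replicates = 4000,
                         effect_size = 0, dispersion = 0.05, libsize_cv = 0,
                         baseline_meanlog = log(200), baseline_sdlog = 0.5,
                         seed = 21)
  mu_hat <- unname(rowMeans(sim$counts$counts))
  v_hat <- apply(sim$counts$counts, 1, var)
  expect_equal(mu_hat, sim$truth$baseline, tolerance = 0.05)
  v_theory <- mu_hat + 0.05 * mu_hat^2
  expect_lt(max(abs(v_hat / v_theory - 1)), 0.10)
})

test_that("bad generator arguments are rejected", {
  w <- stats::setNames(rep(1 / 26, 26), setdiff(trajectory_categories(3), "ns_ns_ns"))
  expect_error(simulate_counts(10, category_weights = w * 0.9), "sum to 1")
  expect_error(simulate_counts(10, replicates = 0), "at least 1 replicate")
})

test_that("drop_replicates keeps other samples untouched and is deterministic", {
  sim <- simulate_counts(30, seed = 6)
  expect_identical(drop_replicates(sim$counts, "1", keep = 4), sim$counts)
  thin <- drop_replicates(sim$counts, "1", keep = 1, seed = 5)
  expect_identical(n_samples(thin), 13L)
  expect_identical(sum(thin$samples$stage == "1"), 1L)
  others <- sim$counts$samples$stage != "1"
  expect_identical(thin$counts[, thin$samples$stage != "1"],
                   sim$counts$counts[, others])
  thin2 <- drop_replicates(sim$counts, "1", keep = 1, seed = 5)
  expect_identical(thin$samples$sample, thin2$samples$sample)
  expect_error(drop_replicates(sim$counts, "99", keep = 1), "absent")
  expect_error(drop_replicates(sim$counts, "1", keep = 9), "keep must be")
})

test_that("planted annotations hit the target category; no terms means empty", {
  sim <- simulate_counts(400, effect_size = 2, seed = 9)
  ann <- simulate_annotations(sim$truth, n_terms = 0,
                              planted = list(list(term = "GO:PLANT",
                                                  category = "up_ns_ns",
                                                  odds = Inf)),
                              seed = 2)
  carriers <- names(ann$genes)[vapply(ann$genes, function(t) "GO:PLANT" %in% t, TRUE)]
  inside <- sim$truth$gene[sim$truth$category_ar == "up_ns_ns"]
  expect_true(all(carriers %in% inside))
  expect_gt(length(carriers), 0)
  empty <- simulate_annotations(sim$truth, n_terms = 0, seed = 2)
  expect_identical(n_annotation_pairs(empty), 0L)
  expect_error(simulate_annotations(sim$truth, planted = list(
    list(term = "A", category = "up_ns_ns", odds = 2),
    list(term = "A", category = "down_ns_ns", odds = 2)), seed = 1),
    "duplicated")
})
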