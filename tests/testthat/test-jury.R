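test_that("contrast designs follow the AR and TC schemes", {
  ar <- build_contrasts(c("35", "15", "5", "1"), "AR")
  expect_identical(ar$label, c("Early", "Middle", "Late"))
  expect_identical(ar$test, c("15", "5", "1"))
  expect_true(all(ar$ref == "35"))
  tc <- build_contrasts(c("35", "15", "5", "1"), "TC")
  expect_identical(tc$test, c("15", "5", "1"))
  expect_identical(tc$ref, c("35", "15", "5"))
  two_ar <- build_contrasts(c("35", "15"), "AR")
  two_tc <- build_contrasts(c("35", "15"), "TC")
  expect_identical(two_ar$test, two_tc$test)
  expect_identical(two_ar$ref, two_tc$ref)
  expect_identical(two_ar$label, "Early")
  expect_error(build_contrasts("35", "AR"), "at least 2 stages")
})

test_that("jury union and intersection follow the worked set-algebra example", {
  genes <- c("a", "b", "c", "d")
  mk <- function(up) {
    m <- matrix("ns", 4, 1, dimnames = list(genes, NULL))
    m[up, 1] <- "up"
    m
  }
  tabs <- list(fake_de_table(genes, "Early", mk(c("a", "b")), "exact-nb"),
               fake_de_table(genes, "Early", mk(c("b", "c")), "nb-wald"),
               fake_de_table(genes, "Early", mk("b"), "voom-lm"))
  jury <- jury_aggregate(tabs)
  expect_setequal(jury$gene[jury$J1 == "up"], c("a", "b", "c"))
  expect_identical(jury$gene[jury$J3 == "up"], "b")
  ct <- combination_table(jury, "Early")
  expect_identical(attr(ct, "j1"), 3L)
  expect_identical(ct$pct[ct$combination == "exact-nb,nb-wald,voom-lm"], 33)
  expect_identical(ct$pct[ct$combination == "exact-nb"], 33)
  expect_identical(ct$pct[ct$combination == "nb-wald"], 33)
  expect_identical(sum(ct$n), 3L)

  # identical callers collapse J1 onto J3
  same <- list(fake_de_table(genes, "Early", mk(c("a", "b")), "exact-nb"),
               fake_de_table(genes, "Early", mk(c("a", "b")), "nb-wald"),
               fake_de_table(genes, "Early", mk(c("a", "b")), "voom-lm"))
  j2 <- jury_aggregate(same)
  expect_identical(j2$J1, j2$J3)
})

test_that("direction conflicts resolve to ns with a flag", {
  genes <- c("a", "b")
  up <- matrix(c("up", "ns"), 2, dimnames = list(genes, NULL))
  dn <- matrix(c("down", "ns"), 2, dimnames = list(genes, NULL))
  jury <- jury_aggregate(list(fake_de_table(genes, "Early", up, "exact-nb"),
                              fake_de_table(genes, "Early", dn, "nb-wald"),
                              fake_de_table(genes, "Early", up, "voom-lm")))
  expect_identical(jury$J1[jury$gene == "a"], "ns")
  expect_true(jury$conflict[jury$gene == "a"])
  expect_identical(jury$J3[jury$gene == "a"], "ns")
})

test_that("mismatched gene sets across callers are an error", {
  a <- fake_de_table(c("a", "b"), "Early", matrix("ns", 2, 1), "exact-nb")
  b <- fake_de_table(c("a", "x"), "Early", matrix("ns", 2, 1), "nb-wald")
  expect_error(jury_aggregate(list(a, b)), "different genes")
})

test_that("jury subset and partition invariants hold on randomized fixtures", {
  contrasts <- c("Early", "Middle", "Late")
  for (seed in 1:6) {
    tabs <- lapply(c("exact-nb", "nb-wald", "voom-lm"), function(cl)
      fake_de_table(sprintf("g%03d", 1:60), contrasts,
                    random_call_matrix(60, 3, seed * 100 + match(cl, c("exact-nb", "nb-wald", "voom-lm"))),
                    cl))
    jury <- jury_aggregate(tabs)
    for (ct in contrasts) {
      sub <- jury[jury$contrast == ct, ]
      for (dir in c("up", "down")) {
        j3 <- sub$gene[sub$J3 == dir]
        j1 <- sub$gene[sub$J1 == dir]
        for (cl in c("exact-nb", "nb-wald", "voom-lm")) {
          caller_set <- sub$gene[sub[[cl]] == dir]
          expect_true(all(j3 %in% caller_set))
          expect_true(all(setdiff(caller_set, sub$gene[sub$conflict]) %in% j1))
        }
      }
      tab <- combination_table(jury, ct)
      expect_identical(sum(tab$n), sum(sub$J1 != "ns" | sub$conflict))
      if (attr(tab, "j1") > 0)
        expect_lt(abs(sum(tab$pct) - 100), 4)  # rounding slack over 7 cells
    }
    # trajectory assignment partitions the gene universe
    asg <- assign_trajectories(jury)
    for (m in attr(jury, "methods")) {
      sub <- asg[asg$method == m, ]
      expect_identical(sort(sub$gene), sort(unique(jury$gene)))
      expect_identical(anyDuplicated(sub$gene), 0L)
      expect_true(all(sub$category %in% trajectory_categories(3)))
    }
  }
})

test_that("min J3 percentage equals the brute-force minimum of ratios", {
  expect_identical(min_j3_percentage(c(1050, 1838, 1860, 3762, 2701),
                                     c(642, 1195, 1290, 3024, 2065)), 61L)
  expect_identical(min_j3_percentage(100, 100), 100L)
  set.seed(11)
  for (i in 1:10) {
    j1 <- sample(50:500, 5)
    j3 <- vapply(j1, function(n) sample(0:n, 1), 1L)
    oracle <- as.integer(min(floor(100 * j3 / j1 + 0.5)))
    expect_identical(min_j3_percentage(j1, j3), oracle)
  }
  expect_error(min_j3_percentage(c(0, 0), c(0, 0)), "empty J1")
})
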