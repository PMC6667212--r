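test_that("low-count filter keeps exactly the genes a brute-force scan keeps", {
  set.seed(3)
  counts <- matrix(rpois(200 * 6, 2), 200)
  counts[1, ] <- 0
  cm <- make_cm(counts, stages = rep(c("35", "15"), each = 3))
  expect_identical(filter_low_counts(cm, 0)$counts, cm$counts)
  f1 <- filter_low_counts(cm, 1)
  expect_false("g001" %in% rownames(f1$counts))
  for (mc in c(1L, 3L, 5L)) {
    keep_oracle <- rownames(cm$counts)[sapply(seq_len(nrow(counts)), function(i)
      any(counts[i, ] >= mc))]
    expect_identical(rownames(filter_low_counts(cm, mc)$counts), keep_oracle)
  }
})

test_that("TMM factors: identical columns give 1, doubled column doubles its factor", {
  base <- rpois(500, 50) + 1
  cm <- make_cm(cbind(base, base, base, base), rep(c("35", "15"), each = 2))
  expect_equal(as.numeric(tmm_factors(cm)), rep(1, 4), tolerance = 1e-12)
  cm2 <- make_cm(cbind(base, 2 * base), c("35", "15"))
  f <- as.numeric(tmm_factors(cm2))
  expect_equal(f[2] / f[1], 2, tolerance = 1e-9)
  expect_equal(f, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-9)
})

test_that("TMM equals an independently coded trimmed weighted mean", {
  set.seed(7)
  # large distinct counts so the trim boundaries are tie-free
  c1 <- sample(500:50000, 800)
  c2 <- round(c1 * runif(800, 0.5, 2))
  counts <- cbind(c1, c2)
  cm <- make_cm(counts, c("35", "15"))
  f <- as.numeric(tmm_factors(cm))
  # naive oracle, written independently: loops and sort() instead of rank()
  lib <- colSums(counts)
  x <- counts[, 2]; r <- counts[, 1]
  m <- log2((x / lib[2]) / (r / lib[1]))
  a <- 0.5 * log2((x / lib[2]) * (r / lib[1]))
  w <- (lib[2] - x) / (lib[2] * x) + (lib[1] - r) / (lib[1] * r)
  n <- length(m)
  keep <- rep(TRUE, n)
  ord_m <- order(m); ord_a <- order(a)
  cut_m <- floor(n * 0.3); cut_a <- floor(n * 0.05)
  keep[ord_m[seq_len(cut_m)]] <- FALSE
  keep[ord_m[n + 1 - seq_len(cut_m)]] <- FALSE
  keep[ord_a[seq_len(cut_a)]] <- FALSE
  keep[ord_a[n + 1 - seq_len(cut_a)]] <- FALSE
  adj <- 2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  fac <- lib * c(1, adj)
  fac <- fac / exp(mean(log(fac)))
  # which column is the reference depends on upper quartiles; accept either
  expect_true(max(abs(f / fac - 1)) < 1e-9 ||
                max(abs(rev(f) / rev(fac) - 1)) < 1e-9)
  skip_if_not_installed("edgeR")
  nf <- edgeR::calcNormFactors(cm$counts, method = "TMM") * colSums(cm$counts)
  expect_equal(f, unname(nf / exp(mean(log(nf)))), tolerance = 1e-10)
})

test_that("RLE factors match the brute-force median of ratios", {
  base <- rpois(300, 40) + 1
  cm <- make_cm(cbind(base, base, base), c("35", "15", "5"))
  expect_equal(as.numeric(rle_size_factors(cm)), rep(1, 3), tolerance = 1e-12)
  cm2 <- make_cm(cbind(base, 3 * base), c("35", "15"))
  f <- as.numeric(rle_size_factors(cm2))
  expect_equal(f[2] / f[1], 3, tolerance = 1e-12)
  set.seed(9)
  counts <- matrix(rpois(400 * 4, 30) + 1, ncol = 4)
  cm3 <- make_cm(counts, rep(c("35", "15"), each = 2))
  f3 <- as.numeric(rle_size_factors(cm3))
  geo <- apply(counts, 1, function(x) prod(x)^(1 / length(x)))
  oracle <- apply(counts / geo, 2, median)
  expect_equal(f3, oracle, tolerance = 1e-9)
  zero <- make_cm(matrix(c(0, 1, 1, 0), 2), c("35", "15"))
  expect_error(rle_size_factors(zero), "filter")
})

test_that("rlog-like transform is monotone, flat on constants, log-like at high counts", {
  cm <- make_cm(matrix(c(7, 7, 7, 7), 1), rep(c("35", "15"), each = 2))
  tr <- rlog_like(cm)
  expect_true(all(tr == tr[1]))
  set.seed(2)
  counts <- matrix(rpois(100 * 4, rep(c(5, 5000), 50)), ncol = 4)
  cm2 <- make_cm(counts, rep(c("35", "15"), each = 2))
  tr2 <- rlog_like(cm2)
  z <- sweep(cm2$counts, 2, as.numeric(rle_size_factors(cm2)), "/")
  plain <- log2(z + 1)
  high <- rowMeans(z) > 1000
  expect_lt(max(abs(tr2[high, ] / plain[high, ] - 1)), 0.01)
  # monotone within gene
  for (g in 1:20) {
    o <- order(z[g, ])
    expect_true(all(diff(tr2[g, o]) >= -1e-12))
  }
})
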