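make_means <- function(n = 12, k = 6, d = 2, seed = 10) {
  set.seed(seed)
  arr <- array(rnorm(k * d * n, sd = 0.1), c(k, d, n),
               dimnames = list(NULL, c("x", "y", "z")[1:d],
                               paste0("sp", seq_len(n))))
  base <- matrix(seq_len(k * d), k, d)
  for (i in seq_len(n)) arr[, , i] <- arr[, , i] + base
  arr
}

test_that("variance along a single direction loads entirely on PC1", {
  k <- 4; n <- 8
  dir <- matrix(rnorm(k * 2), k, 2)
  arr <- array(NA_real_, c(k, 2, n),
               dimnames = list(NULL, NULL, paste0("sp", 1:n)))
  for (i in 1:n) arr[, , i] <- i * dir
  p <- shape_pca(arr)
  expect_equal(p$proportion[[1]], 1, tolerance = 1e-10)
})

test_that("full-rank scores preserve pairwise distances among shapes", {
  arr <- make_means()
  p <- shape_pca(arr)
  flat <- morphmod:::flatten_shapes(arr)
  expect_equal(unname(as.matrix(dist(p$scores))),
               unname(as.matrix(dist(flat))), tolerance = 1e-8)
})

test_that("variance proportions match a dense eigendecomposition oracle", {
  arr <- make_means(n = 15, k = 5)
  p <- shape_pca(arr)
  flat <- morphmod:::flatten_shapes(arr)
  ev <- eigen(cov(flat), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-10]
  expect_equal(p$eigenvalues, ev, tolerance = 1e-8)
  expect_equal(p$proportion, ev / sum(ev), tolerance = 1e-8)
  expect_equal(sum(p$proportion), 1, tolerance = 1e-10)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(unname(colMeans(p$scores)), rep(0, ncol(p$scores)),
               tolerance = 1e-10)
})

test_that("PCA needs at least two species", {
  expect_error(shape_pca(make_means(n = 1)), "at least 2")
})

test_that("broken-stick counts follow the segment-expectation formula", {
  # p = 3: expectations (0.6111, 0.2778, 0.1111)
  expect_equal(broken_stick_axes(c(0.7, 0.2, 0.1)), 1L)
  # uniform proportions never exceed the expectation
  expect_equal(broken_stick_axes(rep(1 / 6, 6)), 0L)
  # counting stops at the first non-significant axis
  expect_equal(broken_stick_axes(c(0.65, 0.3, 0.05)), 2L)
  expect_error(broken_stick_axes(c(0.2, 0.7, 0.1)), "sorted")
})

test_that("PC1 significance is monotone in its variance share", {
  # once the leading axis beats its broken-stick expectation, inflating its
  # share (renormalizing the rest) can never turn it non-significant
  set.seed(11)
  base <- sort(runif(8), decreasing = TRUE)
  base <- base / sum(base)
  sig1 <- sapply(seq(0, 0.6, by = 0.1), function(extra) {
    p <- base * (1 - extra)
    p[1] <- p[1] + extra
    broken_stick_axes(sort(p, decreasing = TRUE)) >= 1
  })
  first <- match(TRUE, sig1)
  expect_true(all(sig1[first:length(sig1)]))
})

test_that("backtransform reproduces the mean, each species, and is linear", {
  arr <- make_means()
  p <- shape_pca(arr)
  expect_equal(backtransform_shape(p, numeric(0)), p$mean_shape,
               tolerance = 1e-12)
  bt <- backtransform_shape(p, p$scores["sp3", ])
  expect_equal(unname(bt), unname(arr[, , "sp3"]), tolerance = 1e-10)
  s <- c(PC1 = 0.02, PC2 = -0.01)
  d1 <- backtransform_shape(p, s) - p$mean_shape
  d2 <- backtransform_shape(p, 2 * s) - p$mean_shape
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
})

test_that("full-axis reconstruction is lossless", {
  arr <- make_means(n = 10, k = 7)
  p <- shape_pca(arr)
  for (sp in c("sp1", "sp6")) {
    bt <- backtransform_shape(p, p$scores[sp, ])
    expect_lt(max(abs(bt - arr[, , sp])), 1e-8)
  }
})

test_that("phylomorphospace places ancestors by GLS and lists edges", {
  # two tips, equal branches: root at the midpoint
  arr <- make_means(n = 2, k = 4)
  dimnames(arr)[[3]] <- c("A", "B")
  p <- shape_pca(arr)
  pm <- phylomorphospace(p, cherry_tree(), axes = 1)
  expect_equal(unname(pm$node_scores[1, 1]),
               mean(p$scores[c("A", "B"), 1]), tolerance = 1e-10)

  # star tree: root at the tip mean (GLS closed form for equal branches)
  star <- read_shape_tree("(A:1,B:1,C:1,D:1);")
  arr4 <- make_means(n = 4, k = 4)
  dimnames(arr4)[[3]] <- c("A", "B", "C", "D")
  p4 <- shape_pca(arr4)
  pm4 <- phylomorphospace(p4, star)
  expect_equal(unname(pm4$node_scores[1, ]),
               unname(colMeans(p4$scores[star$tip.label, 1:2])),
               tolerance = 1e-10)
  expect_equal(nrow(pm4$edges), nrow(star$edge))

  expect_error(phylomorphospace(p4, read_shape_tree("(A:1,Z:1);")), "absent")
})
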