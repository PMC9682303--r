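test_that("a single configuration aligns to itself", {
  a <- triangle_a()
  fit <- gpa_align(array(a, c(3, 2, 1)))
  expect_equal(unname(colMeans(fit$coords[, , 1])), c(0, 0), tolerance = 1e-12)
  expect_equal(sum(fit$coords[, , 1]^2), 1, tolerance = 1e-12)
  expect_equal(fit$consensus, fit$coords[, , 1], tolerance = 1e-12)
})

test_that("similarity-transformed copies superimpose exactly", {
  a <- triangle_a()
  b <- similarity_transform(a, angle = 0.7, scale = 3.2, shift = c(5, -2))
  fit <- gpa_align(array(c(a, b), c(3, 2, 2)))
  expect_lt(procrustes_distance(fit$coords[, , 1], fit$coords[, , 2]), 1e-8)
})

test_that("Procrustes distance matches the SVD and grid-search oracles", {
  a <- triangle_a(); b <- triangle_b()
  d_pkg <- procrustes_distance(a, b)
  expect_equal(d_pkg, procrustes_distance_svd(a, b), tolerance = 1e-10)
  expect_equal(d_pkg, procrustes_distance_grid(a, b), tolerance = 1e-4)
  # symmetry on random pairs
  set.seed(42)
  for (i in 1:5) {
    x <- matrix(rnorm(8), 4, 2); y <- matrix(rnorm(8), 4, 2)
    expect_equal(procrustes_distance(x, y), procrustes_distance(y, x),
                 tolerance = 1e-12)
  }
  expect_equal(procrustes_distance(a, a), 0, tolerance = 1e-8)
})

test_that("degenerate configurations are rejected by name", {
  flat <- array(0, c(3, 2, 2), dimnames = list(NULL, NULL, c("ok", "bad")))
  flat[, , 1] <- triangle_a()
  expect_error(gpa_align(flat), "bad")
  expect_error(procrustes_distance(matrix(1, 3, 2), triangle_a()),
               "degenerate")
})

test_that("alignment is invariant to arbitrary similarity transforms of inputs", {
  set.seed(3)
  n <- 6
  base <- matrix(rnorm(10 * 2), 10, 2)
  arr1 <- array(NA_real_, c(10, 2, n))
  arr2 <- array(NA_real_, c(10, 2, n))
  for (i in 1:n) {
    cfg <- base + matrix(rnorm(20, sd = 0.05), 10, 2)
    arr1[, , i] <- cfg
    arr2[, , i] <- similarity_transform(cfg, runif(1, 0, 2 * pi),
                                        runif(1, 0.5, 4), rnorm(2, sd = 10))
  }
  f1 <- gpa_align(arr1); f2 <- gpa_align(arr2)
  expect_equal(f1$coords, f2$coords, tolerance = 1e-8)
})

test_that("residual sum of squares never increases across iterations", {
  set.seed(4)
  arr <- array(rnorm(8 * 2 * 12, sd = 1), c(8, 2, 12))
  for (i in 1:12) arr[, , i] <- triangle_a()[c(1, 2, 3, 1, 2, 3, 1, 2), ] * 0 +
    matrix(rnorm(16), 8, 2)
  fit <- gpa_align(arr, tol = 0)   # run to max_iter to observe the path
  expect_true(all(diff(fit$rss) <= 1e-12))
})

test_that("species means average aligned specimens and ignore specimen order", {
  set.seed(5)
  arr <- array(NA_real_, c(4, 2, 6),
               dimnames = list(NULL, NULL, paste0(rep(c("A", "B", "C"), 2), "_",
                                                 rep(1:2, each = 3))))
  for (i in 1:6) arr[, , i] <- matrix(rnorm(8), 4, 2)
  x <- landmark_set(arr, dimnames(arr)[[3]])
  fit <- gpa_align(x)
  means <- species_mean_shapes(fit)
  expect_equal(means$species, c("A", "B", "C"))
  idx <- which(fit$species == "B")
  manual <- apply(fit$coords[, , idx], c(1, 2), mean)
  manual <- sweep(manual, 2, colMeans(manual))
  expect_equal(unname(means$coords[, , "B"]), unname(manual), tolerance = 1e-12)

  perm <- sample(6)
  x2 <- landmark_set(arr[, , perm], dimnames(arr)[[3]][perm])
  means2 <- species_mean_shapes(gpa_align(x2))
  expect_equal(means2$coords, means$coords, tolerance = 1e-10)
})

test_that("singleton species pass through as their own aligned shape", {
  arr <- array(c(triangle_a(), triangle_b()), c(3, 2, 2),
               dimnames = list(NULL, NULL, c("A_1", "B_1")))
  fit <- gpa_align(landmark_set(arr, c("A_1", "B_1")))
  means <- species_mean_shapes(fit)
  expect_equal(unname(means$coords[, , "A"]), unname(fit$coords[, , 1]),
               tolerance = 1e-12)
})
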