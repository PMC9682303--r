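# landmark-level partition used throughout: k landmarks in d dims, halves
half_map <- function(k) module_map(rep(c("left", "right"), each = k / 2))

test_that("zero between-block covariance gives CR = 0", {
  set.seed(30)
  n <- 40
  A <- matrix(rnorm(n * 4), n, 4)
  B <- matrix(rnorm(n * 4), n, 4)
  # orthogonalize block B against block A sample-wise: exact zero covariance
  B <- qr.resid(qr(cbind(1, A)), B)
  Y <- cbind(A, B)
  expect_equal(covariance_ratio(Y, half_map(8), d = 1), 0, tolerance = 1e-12)
})

test_that("a duplicated module pushes CR to or above one", {
  set.seed(31)
  A <- matrix(rnorm(50 * 5), 50, 5)
  Y <- cbind(A, A)
  cr <- covariance_ratio(Y, half_map(10), d = 1)
  expect_gte(cr, 1)
  # verified against the block-trace formula written out directly
  S <- cov(Y)
  S12 <- S[1:5, 6:10]; S11 <- S[1:5, 1:5]; S22 <- S[6:10, 6:10]
  diag(S11) <- 0; diag(S22) <- 0
  oracle <- sqrt(sum(S12^2) / sqrt(sum(S11^2) * sum(S22^2)))
  expect_equal(cr, oracle, tolerance = 1e-12)
})

test_that("CR is invariant to landmark order within modules and relabeling", {
  set.seed(32)
  Y <- matrix(rnorm(30 * 12), 30, 12)
  map <- module_map(rep(c("a", "b", "c"), each = 2))  # 6 landmarks, d = 2
  cr0 <- covariance_ratio(Y, map, d = 2)
  # permute landmarks within modules (landmarks 1-2, 3-4, 5-6)
  perm_lm <- c(2, 1, 4, 3, 6, 5)
  cols <- as.vector(vapply(perm_lm, function(j) c(2 * j - 1, 2 * j), numeric(2)))
  expect_equal(covariance_ratio(Y[, cols], map, d = 2), cr0, tolerance = 1e-12)
  # relabel modules
  map2 <- module_map(rep(c("z", "q", "m"), each = 2))
  expect_equal(covariance_ratio(Y, map2, d = 2), cr0, tolerance = 1e-12)
})

test_that("modularity test on two modules matches the battery comparison", {
  set.seed(33)
  tr <- simulate_pure_birth_tree(20, 33)
  spec <- sim_spec(n_species = 20, k = 8, d = 2, module_sizes = c(4, 4),
                   seed = 33)
  Y <- simulate_species_traits(spec, tr)
  map <- sim_module_map(spec)
  mt <- modularity_test(Y, map, tree = tr, n_perm = 199, d = 2, seed = 1)
  cmp <- compare_cr_models(Y, list(two = map, one = module_map(rep("all", 8))),
                           tree = tr, n_perm = 199, d = 2, seed = 1)
  expect_equal(mt$cr, cmp$table$cr[cmp$table$model == "two"], tolerance = 1e-12)
  expect_true(is.na(cmp$table$cr[cmp$table$model == "one"]))
})

test_that("modularity test flags clearly modular data as significant", {
  tr <- simulate_pure_birth_tree(50, 34)
  hits <- 0
  for (i in 1:10) {
    spec <- sim_spec(n_species = 50, k = 20, d = 2,
                     module_sizes = c(10, 10), within_module_corr = 0.7,
                     between_module_corr = 0.1, seed = 600 + i)
    Y <- simulate_species_traits(spec, tr)
    mt <- modularity_test(Y, sim_module_map(spec), tree = tr, n_perm = 100,
                          d = 2, seed = i)
    hits <- hits + (mt$p <= 0.05)
  }
  expect_gte(hits, 9)
})

test_that("small permutation counts trigger a warning", {
  set.seed(35)
  Y <- matrix(rnorm(20 * 8), 20, 8)
  expect_warning(modularity_test(Y, half_map(8), n_perm = 50, d = 1),
                 "n_perm")
})

test_that("a rotated, rescaled copy of one block yields full integration", {
  set.seed(36)
  A <- matrix(rnorm(30 * 6), 30, 6)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))   # orthogonal image + shift + scale
  Y <- cbind(A, 1.7 * A %*% Q + 2)
  res <- integration_test(Y, half_map(12), n_perm = 49, d = 1, seed = 1)
  expect_equal(res$rpls, 1, tolerance = 1e-10)
})

test_that("rPLS is invariant to orthogonal rotation of either block", {
  set.seed(37)
  Y <- matrix(rnorm(25 * 10), 25, 10)
  map <- half_map(10)
  r0 <- integration_test(Y, map, n_perm = 9, d = 1, seed = 1)$rpls
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  Y2 <- cbind(Y[, 1:5] %*% Q, Y[, 6:10])
  expect_equal(integration_test(Y2, map, n_perm = 9, d = 1, seed = 1)$rpls,
               r0, tolerance = 1e-10)
})

test_that("independent blocks show weak, non-significant integration", {
  tr <- simulate_pure_birth_tree(200, 38)
  set.seed(38)
  res <- replicate(8, {
    spec <- sim_spec(n_species = 200, k = 12, d = 2, module_sizes = c(6, 6),
                     within_module_corr = 0.5, between_module_corr = 0,
                     seed = sample.int(1e6, 1))
    Y <- simulate_species_traits(spec, tr)
    it <- integration_test(Y, sim_module_map(spec), tree = tr, n_perm = 99,
                           d = 2, seed = 2)
    c(it$rpls, it$p)
  })
  expect_gte(mean(res[1, ] < 0.3), 0.85)
  expect_gte(mean(res[2, ] > 0.05), 0.85)
})

test_that("degenerate blocks are reported by module name", {
  Y <- cbind(matrix(rnorm(40), 10, 4), matrix(0, 10, 4))
  expect_error(integration_test(Y, half_map(8), d = 1), "right")
})
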