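test_that("identical data in every module gives a rate ratio of exactly one", {
  tr <- simulate_pure_birth_tree(15, 50)
  set.seed(50)
  block <- matrix(rnorm(15 * 4), 15, 4)
  Y <- cbind(block, block)
  rownames(Y) <- tr$tip.label
  map <- module_map(rep(c("a", "b"), each = 4))
  res <- module_rate_ratio_test(Y, map, tr, n_sim = 19, d = 1, seed = 1)
  expect_equal(res$ratio, 1, tolerance = 1e-12)
})

test_that("rate estimates scale inversely with branch lengths, ratio unchanged", {
  tr <- simulate_pure_birth_tree(20, 51)
  spec <- sim_spec(n_species = 20, k = 8, d = 2, module_sizes = c(4, 4),
                   rate_multipliers = c(3, 1), seed = 51)
  Y <- simulate_species_traits(spec, tr)
  map <- sim_module_map(spec)
  r1 <- module_rate_ratio_test(Y, map, tr, n_sim = 19, d = 2, seed = 1)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 2
  r2 <- module_rate_ratio_test(Y, map, tr2, n_sim = 19, d = 2, seed = 1)
  expect_equal(r2$sigma2_per_module, r1$sigma2_per_module / 2,
               tolerance = 1e-10)
  expect_equal(r2$ratio, r1$ratio, tolerance = 1e-10)
})

test_that("rate ratio is invariant to module relabeling", {
  tr <- simulate_pure_birth_tree(20, 52)
  spec <- sim_spec(n_species = 20, k = 8, d = 2, module_sizes = c(4, 4),
                   seed = 52)
  Y <- simulate_species_traits(spec, tr)
  m1 <- module_map(rep(c("a", "b"), each = 4))
  m2 <- module_map(rep(c("b", "a"), each = 4))
  r1 <- module_rate_ratio_test(Y, m1, tr, n_sim = 9, d = 2, seed = 1)
  r2 <- module_rate_ratio_test(Y, m2, tr, n_sim = 9, d = 2, seed = 1)
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
})

test_that("a five-fold faster module is detected with a calibrated ratio", {
  tr <- simulate_pure_birth_tree(50, 53)
  set.seed(53)
  out <- replicate(12, {
    spec <- sim_spec(n_species = 50, k = 20, d = 2,
                     module_sizes = c(5, 5, 5, 5),
                     rate_multipliers = c(5, 1, 1, 1),
                     seed = sample.int(1e6, 1))
    Y <- simulate_species_traits(spec, tr)
    res <- module_rate_ratio_test(Y, sim_module_map(spec), tr, n_sim = 99,
                                  d = 2, seed = 3)
    c(res$ratio, res$p)
  })
  expect_gte(median(out[1, ]), 3.5)
  expect_lte(median(out[1, ]), 6.5)
  expect_gte(mean(out[2, ] <= 0.05), 0.9)
})

test_that("a huge smoothing penalty collapses multirate BM to the single rate", {
  tr <- simulate_pure_birth_tree(12, 54)
  set.seed(54)
  y <- setNames(drop(bm_tips(tr, matrix(1))), tr$tip.label)
  fit <- multirate_bm(y, tr, lambda = 1e6)
  expect_lt(max(abs(fit$edge_rates / fit$sig2_single - 1)), 0.01)
})

test_that("rate-profile variance is non-increasing in the smoothing penalty", {
  tr <- simulate_pure_birth_tree(16, 55)
  set.seed(55)
  # heterogeneous truth: inflate one clade's branches
  tr2 <- tr
  desc <- ape::extract.clade(tr, 18)$tip.label
  y <- setNames(drop(bm_tips(tr, matrix(1))), tr$tip.label)
  y[desc] <- y[desc] * 4
  v <- vapply(c(0.1, 1, 10), function(l) {
    var(multirate_bm(y, tr, lambda = l)$log_rates)
  }, numeric(1))
  expect_true(all(diff(v) <= 1e-8))
})

test_that("constant-rate traits recover a flat rate profile", {
  tr <- simulate_pure_birth_tree(24, 56)
  set.seed(56)
  sds <- replicate(6, {
    y <- setNames(drop(bm_tips(tr, matrix(1))), tr$tip.label)
    sd(multirate_bm(y, tr, lambda = 1)$log_rates)
  })
  expect_lt(median(sds), 0.5)
})

test_that("a two-tip tree reproduces the closed-form likelihood", {
  tr <- cherry_tree()
  y <- c(A = 0, B = 1.2)
  fit <- multirate_bm(y, tr, lambda = 1e8)
  s2 <- fit$sig2_single
  # closed form: ML single rate for two tips at depth 1 each
  # contrast (yA - yB) ~ N(0, 2 sigma^2); GLS mean = (yA+yB)/2
  expect_equal(s2, (0.6^2 + 0.6^2) / 2, tolerance = 1e-8)
  ll_direct <- sum(dnorm(c(0, 1.2), mean = 0.6, sd = sqrt(s2), log = TRUE)) -
    0  # independent tips on a cherry: C = s2 * I
  expect_equal(fit$logL, ll_direct, tolerance = 1e-4)
})
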