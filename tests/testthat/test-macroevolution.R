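# four-tip tree with two pairs: ((A,B),(C,D))
quartet_tree <- function() read_shape_tree("((A:1,B:1):1,(C:1,D:1):1);")

test_that("identical focal tips with distinct ancestors give C1 = 1", {
  sc <- rbind(A = c(0, 0), B = c(4, 0), C = c(0.0, 0.1), D = c(0, -0.1))
  # A and C end at nearly the same place from different clades
  sc["C", ] <- sc["A", ]
  res <- convergence_c_metrics(sc, quartet_tree(), c("A", "C"), n_sim = 5,
                               seed = 1)
  expect_equal(unname(res$observed["C1"]), 1, tolerance = 1e-10)
  expect_gt(res$observed["C2"], 0)
})

test_that("purely diverging lineages give C1 = 0 and C2 = 0", {
  # tips are the farthest their lineages have ever been
  sc <- rbind(A = c(-4, 0), B = c(-1, 0), C = c(4, 0), D = c(1, 0))
  res <- convergence_c_metrics(sc, quartet_tree(), c("A", "C"), n_sim = 5,
                               seed = 1)
  expect_equal(unname(res$observed["C1"]), 0, tolerance = 1e-8)
  expect_equal(unname(res$observed["C2"]), 0, tolerance = 1e-8)
})

test_that("convergence metrics respect their ranges and rigid motions", {
  tr <- simulate_pure_birth_tree(16, 60)
  set.seed(60)
  sc <- bm_tips(tr, diag(2))
  focal <- tr$tip.label[c(1, 8, 14)]
  res <- convergence_c_metrics(sc, tr, focal, n_sim = 5, seed = 2)
  expect_gte(res$observed["C1"], 0); expect_lte(res$observed["C1"], 1)
  expect_gte(res$observed["C2"], 0)
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  sc2 <- sweep(sc %*% R, 2, c(3, -1), `+`)
  res2 <- convergence_c_metrics(sc2, tr, focal, n_sim = 5, seed = 2)
  expect_equal(res2$observed, res$observed, tolerance = 1e-8)
})

test_that("ellipse crossings count lineages entering the focal region", {
  tr <- quartet_tree()
  sc <- rbind(A = c(0, 0), B = c(0.1, 0.15), C = c(0.05, -0.1),
              D = c(40, 40))
  res <- convnum_ellipse(sc, tr, c("A", "B", "C"))
  # focal tips terminate inside their own ellipse; D ends far outside but its
  # lineage starts at the root (inside region near origin)
  expect_true(all(c("A", "B", "C") %in% res$crossing_tips))
  expect_gt(res$area, 0)

  # translation and rotation leave count and area unchanged
  th <- 0.5
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  sc2 <- sweep(sc %*% R, 2, c(-7, 2), `+`)
  res2 <- convnum_ellipse(sc2, tr, c("A", "B", "C"))
  expect_equal(res2$n_crossing, res$n_crossing)
  expect_equal(res2$area, res$area, tolerance = 1e-6)
})

test_that("a distant non-focal lineage contributes no crossing", {
  # push the whole far clade away so neither its tips nor ancestors nor the
  # root fall inside the focal ellipse
  tr <- read_shape_tree("(((A:1,B:1):1,C:2):1,(D:1,E:1):2);")
  sc <- rbind(A = c(0, 0), B = c(0.1, 0.1), C = c(0.05, -0.05),
              D = c(30, 30), E = c(31, 29))
  res <- convnum_ellipse(sc, tr, c("A", "B", "C"))
  expect_false("D" %in% res$crossing_tips)
  expect_false("E" %in% res$crossing_tips)
  expect_equal(res$n_crossing - res$n_crossing_nonfocal, 3)
})

test_that("degenerate focal sets are rejected with advice", {
  tr <- quartet_tree()
  sc <- rbind(A = c(0, 0), B = c(1, 1), C = c(2, 2), D = c(3, 3))
  expect_error(convnum_ellipse(sc, tr, c("A", "B", "C")), "buffer")
})

test_that("disparity is zero at the root and for identical tips", {
  tr <- simulate_pure_birth_tree(10, 61)
  sc <- matrix(1.5, 10, 2, dimnames = list(tr$tip.label, NULL))
  prof <- disparity_through_time(sc, tr)
  expect_equal(prof$profile$disparity, rep(0, 31), tolerance = 1e-12)

  set.seed(61)
  sc2 <- bm_tips(tr, diag(2))
  prof2 <- disparity_through_time(sc2, tr)
  expect_equal(prof2$profile$disparity[1], 0, tolerance = 1e-12)
  expect_equal(nrow(prof2$profile), 31)
  expect_true(all(diff(prof2$profile$time) > 0))
})

test_that("a two-tip tree matches the closed-form final disparity", {
  tr <- cherry_tree()
  s <- 2.7
  sc <- rbind(A = c(0, 0), B = c(s, 0))
  prof <- disparity_through_time(sc, tr, n_slices = 11)
  expect_equal(prof$profile$disparity[11], s^2, tolerance = 1e-10)
})

test_that("final-slice disparity equals the tips' mean squared distance", {
  tr <- simulate_pure_birth_tree(14, 62)
  set.seed(62)
  sc <- bm_tips(tr, diag(3))
  prof <- disparity_through_time(sc, tr)
  direct <- mean(dist(sc)^2)
  expect_equal(prof$profile$disparity[31], direct, tolerance = 1e-10)
})

test_that("mean disparity increases with time under Brownian motion", {
  tr <- simulate_pure_birth_tree(20, 63)
  set.seed(63)
  profs <- replicate(60, {
    sc <- bm_tips(tr, diag(2))
    disparity_through_time(sc, tr)$profile$disparity
  })
  avg <- rowMeans(profs)
  expect_gt(cor(seq_along(avg), avg, method = "spearman"), 0.95)
})

test_that("non-ultrametric trees are refused for disparity profiles", {
  tr <- read_shape_tree("((A:1,B:2):1,C:5);")
  sc <- rbind(A = c(0, 0), B = c(1, 0), C = c(0, 1))
  expect_error(disparity_through_time(sc, tr), "ultrametric")
})

test_that("burst detection applies a strict threshold to profile steps", {
  prof <- data.frame(time = 0:3, disparity = c(0, 3, 15, 16))
  b <- detect_bursts(prof, threshold = 10)
  expect_equal(nrow(b), 1)
  expect_equal(b$from_index, 2)
  expect_equal(b$delta, 12)

  mono <- data.frame(time = 0:4, disparity = c(0, 10, 20, 30, 40))
  expect_equal(nrow(detect_bursts(mono, threshold = 10)), 0)
  # strictly greater: a step of exactly the threshold is not a burst
  expect_equal(nrow(detect_bursts(
    data.frame(time = 0:1, disparity = c(0, 10)), threshold = 10)), 0)
  # adjacent qualifying intervals are reported separately
  multi <- data.frame(time = 0:3, disparity = c(0, 12, 25, 26))
  expect_equal(nrow(detect_bursts(multi, threshold = 10)), 2)
})
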