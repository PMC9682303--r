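# shared fixtures and independent oracles, built in code

# two distinct triangles used across GPA tests
triangle_a <- function() matrix(c(0, 0, 1, 0, 0.3, 1.2), ncol = 2, byrow = TRUE)
triangle_b <- function() matrix(c(0, 0, 1.4, 0.1, 0.5, 0.8), ncol = 2, byrow = TRUE)

# apply a random similarity transform (rotation + translation + scaling)
similarity_transform <- function(m, angle, scale, shift) {
  R <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2, 2)
  sweep(scale * m %*% R, 2, shift, `+`)
}

# independent Procrustes distance oracle: centre, scale to unit centroid
# size, then brute-force the optimal rotation over a fine grid of angles (2D)
procrustes_distance_grid <- function(a, b, n_grid = 200000L) {
  norm_cfg <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- norm_cfg(a); b <- norm_cfg(b)
  best <- Inf
  for (th in seq(0, 2 * pi, length.out = n_grid)) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    best <- min(best, sum((a %*% R - b)^2))
  }
  sqrt(best)
}

# independent SVD-based Procrustes distance oracle (closed form)
procrustes_distance_svd <- function(a, b) {
  norm_cfg <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- norm_cfg(a); b <- norm_cfg(b)
  s <- svd(t(a) %*% b)
  sig <- c(rep(1, ncol(a) - 1), sign(det(s$u %*% t(s$v))))
  sqrt(max(0, 2 - 2 * sum(s$d * sig)))
}

# phylogenetic covariance oracle by explicit path enumeration
vcv_path_oracle <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- n + 1L
  path_edges <- function(tip) {
    out <- integer(0)
    while (tip != root) { out <- c(out, tip); tip <- parent[tip] }
    out
  }
  paths <- lapply(seq_len(n), path_edges)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    C[i, j] <- sum(elen[intersect(paths[[i]], paths[[j]])])
  }
  C
}

# small fixed trees
cherry_tree <- function() read_shape_tree("(A:1,B:1);")
three_tip_tree <- function() read_shape_tree("((A:1,B:1):1,C:2);")

# quick species x traits BM simulation on a tree with trait covariance R
bm_tips <- function(tree, R, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- phylo_vcv(tree)
  Lc <- t(chol(C))
  er <- eigen(R, symmetric = TRUE)
  Lr <- er$vectors %*% diag(sqrt(pmax(er$values, 0)), ncol(R))
  Y <- Lc %*% matrix(rnorm(nrow(C) * ncol(R)), nrow(C)) %*% t(Lr)
  rownames(Y) <- rownames(C)
  Y
}
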