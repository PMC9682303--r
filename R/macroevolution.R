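# Convergence quantification (Stayton's C1-C4 and morphospace ellipse
# crossings) and disparity-through-time with burst detection.

# node positions (tips then internal) in score space, via BM ancestral states
all_node_positions <- function(tree, scores) {
  sc <- scores[tree$tip.label, , drop = FALSE]
  anc <- ancestral_states_bm(tree, sc)
  n <- length(tree$tip.label)
  pos <- matrix(NA_real_, n + tree$Nnode, ncol(sc))
  pos[seq_len(n), ] <- sc
  pos[(n + 1L):(n + tree$Nnode), ] <- anc
  pos
}

# path of node ids from `from` (ancestor) down to `to` (inclusive of both)
node_path <- function(tree, from, to) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  path <- to
  while (to != from) {
    to <- parent[to]
    path <- c(to, path)
  }
  path
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

# C metrics for one focal pair, given node positions
c_metrics_pair <- function(tree, pos, t1, t2, clade_edges_len) {
  mrca <- ape::getMRCA(tree, c(t1, t2))
  p1 <- node_path(tree, mrca, t1)
  p2 <- node_path(tree, mrca, t2)
  d_tip <- euclid(pos[t1, ], pos[t2, ])
  d_max <- 0
  for (u in p1) for (w in p2) {
    d_uw <- euclid(pos[u, ], pos[w, ])
    if (d_uw > d_max) d_max <- d_uw
  }
  if (d_max == 0) stop("focal taxa never diverged in shape space")
  path_len <- function(p) {
    if (length(p) < 2L) return(0)
    sum(vapply(seq_len(length(p) - 1L),
               function(i) euclid(pos[p[i], ], pos[p[i + 1L], ]), numeric(1L)))
  }
  c2 <- d_max - d_tip
  c(C1 = 1 - d_tip / d_max,
    C2 = c2,
    C3 = c2 / (path_len(p1) + path_len(p2)),
    C4 = c2 / clade_edges_len)
}

c_metrics_observed <- function(tree, scores, focal) {
  pos <- all_node_positions(tree, scores)
  tips <- match(focal, tree$tip.label)
  # total evolution in the clade spanned by the focal taxa: sum of
  # phenotypic change along every edge of that clade's subtree
  span_mrca <- if (length(tips) > 1L) ape::getMRCA(tree, focal) else tips
  clade_nodes <- descendant_nodes(tree, span_mrca)
  e_in <- tree$edge[, 1L] %in% c(span_mrca, clade_nodes) &
    tree$edge[, 2L] %in% clade_nodes
  clade_len <- sum(vapply(which(e_in), function(e) {
    euclid(pos[tree$edge[e, 1L], ], pos[tree$edge[e, 2L], ])
  }, numeric(1L)))
  prs <- utils::combn(tips, 2L)
  vals <- apply(prs, 2L, function(pr)
    c_metrics_pair(tree, pos, pr[1L], pr[2L], clade_len))
  rowMeans(vals)
}

# all nodes (tips and internal) strictly below `node`, plus node itself
descendant_nodes <- function(tree, node) {
  n <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  out <- kids
  for (k in kids) if (k > n) out <- c(out, descendant_nodes(tree, k))
  unique(out)
}

#' Convergence metrics C1-C4 for a set of focal taxa
#'
#' Stayton's distance-ratio measures, computed per focal pair and averaged:
#' with Dtip the phenotypic distance between the two tips and Dmax the
#' maximum distance achieved between any two points (ancestral nodes or tips)
#' along their paths since divergence, `C1 = 1 - Dtip/Dmax` (0 = lineages
#' only ever diverged, 1 = tips identical), `C2 = Dmax - Dtip`,
#' `C3 = C2 / (total phenotypic evolution along the two paths)` and
#' `C4 = C2 / (total phenotypic evolution in the clade spanned by the focal
#' taxa)`. Ancestral positions are Brownian-motion estimates. Significance is
#' the proportion of Brownian-motion simulations (rate matrix estimated from
#' the data) whose metric is at least the observed value.
#'
#' @param scores species x axes score matrix (retained ordination axes)
#' @param tree an [ape::phylo] containing all scored species
#' @param focal_taxa character vector (>= 2) of putatively convergent tips
#' @param n_sim Brownian-motion simulations for the p-values
#' @param seed optional integer seed
#' @return object of class `"convergence_test"`: `observed` (C1-C4), `p`,
#'   `n_sim`, `null` (simulated metrics)
#' @export
convergence_c_metrics <- function(scores, tree, focal_taxa, n_sim = 100L,
                                  seed = NULL) {
  if (length(focal_taxa) < 2L) stop("need at least 2 focal taxa")
  if (!all(focal_taxa %in% tree$tip.label)) {
    stop("focal taxa not on the tree: ",
         paste(setdiff(focal_taxa, tree$tip.label), collapse = ", "))
  }
  scores <- as.matrix(scores)
  obs <- c_metrics_observed(tree, scores, focal_taxa)
  # BM rate matrix estimated from the data for the null simulations
  C <- phylo_vcv(tree)
  sc <- scores[rownames(C), , drop = FALSE]
  U <- phylo_transform(sc, C)
  R <- crossprod(U) / (nrow(U) - 1)
  er <- eigen(R, symmetric = TRUE)
  Lr <- er$vectors %*% diag(sqrt(pmax(er$values, 0)), ncol(R))
  Lc <- t(chol(C))
  a <- phylo_mean(sc, C)
  if (!is.null(seed)) set.seed(seed)
  null <- t(vapply(seq_len(n_sim), function(i) {
    Z <- matrix(stats::rnorm(nrow(C) * ncol(R)), nrow(C), ncol(R))
    sim <- sweep(Lc %*% Z %*% t(Lr), 2L, a, `+`)
    rownames(sim) <- rownames(C)
    c_metrics_observed(tree, sim, focal_taxa)
  }, numeric(4L)))
  p <- colMeans(sweep(null, 2L, obs, `>=`))
  structure(list(observed = obs, p = p, n_sim = n_sim, null = null,
                 focal_taxa = focal_taxa),
            class = "convergence_test")
}

#' @export
print.convergence_test <- function(x, ...) {
  cat("Convergence metrics for {", paste(x$focal_taxa, collapse = ", "),
      "}\n", sep = "")
  for (m in names(x$observed)) {
    cat(sprintf("  %s = %.4f (p = %.3f)\n", m, x$observed[m], x$p[m]))
  }
  cat("  (", x$n_sim, " Brownian-motion simulations)\n", sep = "")
  invisible(x)
}

# minimal-area enclosing ellipse (Khachiyan's algorithm); returns center c and
# shape matrix A with the ellipse {x : (x-c)' A (x-c) <= 1}
min_enclosing_ellipse <- function(P, tol = 1e-7, max_iter = 1000L) {
  P <- as.matrix(P)
  n <- nrow(P); d <- ncol(P)
  if (n < 3L || qr(sweep(P, 2L, colMeans(P)))$rank < d) {
    stop("focal points are degenerate (collinear or too few); ",
         "add a buffer radius or more taxa")
  }
  Q <- t(cbind(P, 1))
  u <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    X <- Q %*% diag(u) %*% t(Q)
    M <- diag(t(Q) %*% solve(X, Q))
    j <- which.max(M)
    step <- (M[j] - d - 1) / ((d + 1) * (M[j] - 1))
    nu <- (1 - step) * u
    nu[j] <- nu[j] + step
    if (sqrt(sum((nu - u)^2)) < tol) { u <- nu; break }
    u <- nu
  }
  ctr <- drop(t(P) %*% u)
  A <- solve(t(P) %*% diag(u) %*% P - outer(ctr, ctr)) / d
  # rescale so every input point satisfies the quadratic form <= 1 exactly
  # (the iteration leaves support points a hair outside otherwise)
  q <- apply(P, 1L, function(x) drop(t(x - ctr) %*% A %*% (x - ctr)))
  A <- A / max(q)
  list(center = ctr, A = A, area = pi / sqrt(det(A)))
}

# does the segment a-b intersect the unit disk centered at origin?
# (small slack so boundary points resolve consistently)
segment_hits_unit_disk <- function(a, b, tol = 1e-9) {
  ab <- b - a
  t <- -sum(a * ab) / sum(ab * ab)
  t <- min(max(t, 0), 1)
  sum((a + t * ab)^2) <= 1 + tol
}

#' Count lineages crossing an ellipse around putatively convergent taxa
#'
#' Places the minimal-area enclosing ellipse around the focal tips' positions
#' in a two-axis morphospace and counts root-to-tip lineages (polylines
#' through the Brownian-motion ancestral positions) that enter it. Lineages
#' of the focal taxa themselves are counted (their terminal point lies inside
#' by construction); the count excluding focal lineages is reported alongside.
#'
#' @param scores species x 2 score matrix (exactly two plotting axes)
#' @param tree an [ape::phylo]
#' @param focal_taxa tips around which the ellipse is placed (>= 3 in general
#'   position)
#' @return object of class `"convnum"`: `n_crossing`, `n_crossing_nonfocal`,
#'   `area`, `crossing_tips`, `ellipse` (center and shape matrix)
#' @export
convnum_ellipse <- function(scores, tree, focal_taxa) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2L) stop("exactly 2 morphospace axes are required")
  if (!all(focal_taxa %in% tree$tip.label)) stop("focal taxa must be on the tree")
  ell <- min_enclosing_ellipse(scores[focal_taxa, , drop = FALSE])
  pos <- all_node_positions(tree, scores)
  n <- length(tree$tip.label)
  root <- n + 1L
  # map to the ellipse's unit-disk frame
  L <- chol(ell$A)
  to_disk <- function(x) drop(L %*% (x - ell$center))
  crossing <- vapply(seq_len(n), function(tip) {
    path <- node_path(tree, root, tip)
    pts <- lapply(path, function(nd) to_disk(pos[nd, ]))
    if (any(vapply(pts, function(z) sum(z^2) <= 1 + 1e-9, logical(1L)))) return(TRUE)
    for (i in seq_len(length(pts) - 1L)) {
      if (segment_hits_unit_disk(pts[[i]], pts[[i + 1L]])) return(TRUE)
    }
    FALSE
  }, logical(1L))
  tips <- tree$tip.label[crossing]
  structure(list(n_crossing = sum(crossing),
                 n_crossing_nonfocal = sum(crossing &
                                             !tree$tip.label %in% focal_taxa),
                 area = ell$area, crossing_tips = tips,
                 ellipse = ell, focal_taxa = focal_taxa),
            class = "convnum")
}

#' @export
print.convnum <- function(x, ...) {
  cat(sprintf("Morphospace ellipse crossings: %d lineages (%d non-focal), ellipse area %.4g\n",
              x$n_crossing, x$n_crossing_nonfocal, x$area))
  invisible(x)
}

#' Disparity through time along a time-calibrated phylogeny
#'
#' At each of `n_slices` evenly spaced times from the root to the present,
#' every branch alive at that time contributes a point linearly interpolated
#' between its parent-node and child-node positions in score space (ancestral
#' positions are Brownian-motion estimates); disparity at the slice is the
#' mean squared pairwise Euclidean distance among those points. The root
#' slice has a single lineage point and disparity 0; at the final slice the
#' profile equals the mean squared pairwise distance among the tips.
#'
#' @param scores species x axes score matrix
#' @param tree ultrametric (time-calibrated) [ape::phylo]
#' @param n_slices number of time points (default 31)
#' @param clade optional label for the profile
#' @param burst_threshold threshold passed to [detect_bursts()]
#' @return object of class `"dtt_profile"`: data frame `profile` with `time`
#'   and `disparity`, plus `bursts`
#' @export
disparity_through_time <- function(scores, tree, n_slices = 31L,
                                   clade = "all", burst_threshold = 10) {
  if (!ape::is.ultrametric(tree, tol = 1e-6)) {
    stop("disparity through time needs an ultrametric (time-calibrated) tree")
  }
  scores <- as.matrix(scores)
  pos <- all_node_positions(tree, scores)
  depth <- node_depths(tree)
  total <- max(depth)
  times <- seq(0, total, length.out = n_slices)
  n <- length(tree$tip.label)
  mean_sq_pairwise <- function(pts) {
    m <- nrow(pts)
    if (m < 2L) return(0)
    mean(stats::dist(pts)^2)
  }
  disp <- vapply(times, function(tt) {
    if (tt >= total - 1e-12) {
      pts <- pos[seq_len(n), , drop = FALSE]
    } else {
      alive <- depth[tree$edge[, 1L]] <= tt & depth[tree$edge[, 2L]] > tt
      pts <- vapply(which(alive), function(e) {
        p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
        span <- depth[ch] - depth[p]
        w <- if (span > 0) (tt - depth[p]) / span else 0
        (1 - w) * pos[p, ] + w * pos[ch, ]
      }, numeric(ncol(pos)))
      pts <- matrix(pts, ncol = ncol(pos), byrow = TRUE)
    }
    mean_sq_pairwise(pts)
  }, numeric(1L))
  profile <- data.frame(time = times, disparity = disp)
  structure(list(profile = profile, clade = clade,
                 bursts = detect_bursts(profile, threshold = burst_threshold),
                 burst_threshold = burst_threshold),
            class = "dtt_profile")
}

#' @export
print.dtt_profile <- function(x, ...) {
  cat("Disparity through time (", x$clade, "): ", nrow(x$profile),
      " slices, final disparity ",
      format(utils::tail(x$profile$disparity, 1L), digits = 5), "\n", sep = "")
  if (nrow(x$bursts)) {
    cat("  bursts (delta > ", x$burst_threshold, "):\n", sep = "")
    print(x$bursts)
  } else cat("  no bursts detected\n")
  invisible(x)
}

#' @export
plot.dtt_profile <- function(x, ...) {
  graphics::plot(x$profile$time, x$profile$disparity, type = "l",
                 xlab = "time since root", ylab = "disparity",
                 main = paste("Disparity through time:", x$clade), ...)
  if (nrow(x$bursts)) {
    graphics::abline(v = x$bursts$to_time, lty = 3, col = "red")
  }
  invisible(x)
}

#' Detect bursts of divergence in a disparity profile
#'
#' A burst is an interval between two subsequent time points whose increase
#' in disparity strictly exceeds the threshold. Adjacent qualifying intervals
#' are reported separately.
#'
#' @param profile a `dtt_profile` or a data frame with `time` and `disparity`
#' @param threshold burst threshold (default 10)
#' @return data frame with one row per burst: `from_index`, `to_index`,
#'   `from_time`, `to_time`, `delta`
#' @export
detect_bursts <- function(profile, threshold = 10) {
  if (inherits(profile, "dtt_profile")) profile <- profile$profile
  if (nrow(profile) == 0L) stop("empty disparity profile")
  delta <- diff(profile$disparity)
  idx <- which(delta > threshold)
  data.frame(from_index = idx, to_index = idx + 1L,
             from_time = profile$time[idx], to_time = profile$time[idx + 1L],
             delta = delta[idx])
}
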