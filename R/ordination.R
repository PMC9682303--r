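# Principal component ordination of species mean shapes, broken-stick axis
# selection, backtransform shapes and phylomorphospace projection.

#' Principal component analysis of species mean shapes
#'
#' Eigen-decomposition (via SVD of the centered, flattened coordinate matrix,
#' covariance denominator n - 1) of the species-mean shape data. No
#' phylogenetic correction is applied, so trends and potential convergence
#' remain visible in the ordination. Axis signs follow a deterministic
#' convention: the largest-magnitude loading of each axis is positive.
#'
#' @param means a [species_mean_shapes()] result, or a `k x d x n` array with
#'   species dimnames
#' @return object of class `"shape_pca"`: `scores` (species x axes),
#'   `eigenvalues`, `proportion` (per-axis fraction of total variance),
#'   `loadings` (`(k*d) x axes`), `mean_shape` (`k x d`), `k`, `d`
#' @export
shape_pca <- function(means) {
  arr <- if (is.list(means) && !is.null(means$coords)) means$coords else means
  k <- dim(arr)[1L]; d <- dim(arr)[2L]; n <- dim(arr)[3L]
  if (n < 2L) stop("PCA needs at least 2 species")
  X <- flatten_shapes(arr)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  s <- svd(Xc)
  pos <- s$d > max(s$d) * 1e-12
  n_ax <- sum(pos)
  eig <- (s$d[pos]^2) / (n - 1)
  load <- s$v[, pos, drop = FALSE]
  for (j in seq_len(n_ax)) {
    v <- load[, j]
    if (v[which.max(abs(v))] < 0) {
      load[, j] <- -v
      s$u[, j] <- -s$u[, j]
    }
  }
  scores <- s$u[, pos, drop = FALSE] %*% diag(s$d[pos], n_ax)
  rownames(scores) <- rownames(X)
  colnames(scores) <- colnames(load) <- paste0("PC", seq_len(n_ax))
  rownames(load) <- colnames(X)
  structure(list(scores = scores, eigenvalues = eig,
                 proportion = eig / sum(eig), loadings = load,
                 mean_shape = matrix(mu, k, d, byrow = TRUE),
                 k = k, d = d, n = n),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("Shape PCA:", x$n, "species,", length(x$eigenvalues), "axes\n")
  p <- utils::head(x$proportion, 5L)
  cat("  variance: ", paste0(names(p), " ", sprintf("%.1f%%", 100 * p),
                             collapse = ", "),
      if (length(x$proportion) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.shape_pca <- function(object, ...) {
  data.frame(axis = seq_along(object$eigenvalues),
             eigenvalue = object$eigenvalues,
             proportion = object$proportion,
             cumulative = cumsum(object$proportion))
}

#' Broken-stick count of significant ordination axes
#'
#' The broken-stick expectation for axis i of p is
#' `b_i = (1/p) * sum_{j=i}^{p} 1/j`. The count is the length of the initial
#' run of axes whose variance proportion strictly exceeds its expectation;
#' counting stops at the first failure so the retained set is contiguous.
#'
#' @param proportions per-axis variance fractions, sorted non-increasing and
#'   summing to about 1; a `shape_pca` may be passed directly
#' @return integer count of significant axes
#' @export
broken_stick_axes <- function(proportions) {
  if (inherits(proportions, "shape_pca")) proportions <- proportions$proportion
  p <- length(proportions)
  if (is.unsorted(rev(proportions), strictly = FALSE)) {
    stop("proportions must be sorted in non-increasing order")
  }
  expect <- rev(cumsum(1 / rev(seq_len(p)))) / p
  above <- proportions > expect
  if (!above[1L]) return(0L)
  which.min(c(above, FALSE)) - 1L
}

#' Backtransform principal component scores to a landmark configuration
#'
#' Reconstructs the theoretical shape at a location in the morphospace:
#' mean shape plus the score-weighted loadings, reshaped to `k x d`.
#'
#' @param space a `shape_pca`
#' @param axis_scores named or positional numeric vector of scores; axes not
#'   mentioned are taken as 0. If unnamed, entries map to PC1, PC2, ...
#' @return `k x d` landmark configuration
#' @export
backtransform_shape <- function(space, axis_scores) {
  stopifnot(inherits(space, "shape_pca"))
  n_ax <- ncol(space$loadings)
  sc <- numeric(n_ax)
  if (!is.null(names(axis_scores))) {
    idx <- match(names(axis_scores), colnames(space$loadings))
    if (anyNA(idx)) stop("unknown axis name")
    sc[idx] <- axis_scores
  } else {
    sc[seq_along(axis_scores)] <- axis_scores
  }
  flat <- as.vector(t(space$mean_shape)) + drop(space$loadings %*% sc)
  unflatten_shapes(flat, space$k, space$d)
}

#' Phylomorphospace: project a phylogeny into the shape ordination
#'
#' Tip positions are the PCA scores; internal-node positions are
#' maximum-likelihood (GLS) Brownian-motion ancestral estimates of the scores,
#' axis by axis (see [ancestral_states_bm()]). Edges are returned as
#' (parent position, child position) pairs for plotting.
#'
#' @param space a `shape_pca`
#' @param tree an [ape::phylo]; tips must all be present among the species in
#'   `space` (prune first with [match_taxa()])
#' @param axes which score axes to project (default first two)
#' @return object of class `"phylomorphospace"`: `tip_scores`, `node_scores`
#'   (internal nodes, rownames = node numbers), `edges` (data frame of segment
#'   endpoints), `tree`
#' @export
phylomorphospace <- function(space, tree, axes = c(1L, 2L)) {
  stopifnot(inherits(space, "shape_pca"))
  missing_tips <- setdiff(tree$tip.label, rownames(space$scores))
  if (length(missing_tips)) {
    stop("tips absent from the shape space: ",
         paste(missing_tips, collapse = ", "), " (prune first)")
  }
  sc <- space$scores[tree$tip.label, axes, drop = FALSE]
  anc <- ancestral_states_bm(tree, sc)
  n <- length(tree$tip.label)
  all_pos <- rbind(sc, anc)  # rows 1..n tips, then internal nodes
  e <- tree$edge
  get_pos <- function(node) {
    if (node <= n) sc[node, , drop = FALSE] else
      anc[as.character(node), , drop = FALSE]
  }
  edges <- do.call(rbind, lapply(seq_len(nrow(e)), function(i) {
    p <- get_pos(e[i, 1L]); c0 <- get_pos(e[i, 2L])
    data.frame(parent = e[i, 1L], child = e[i, 2L],
               x0 = p[1L], y0 = p[2L], x1 = c0[1L], y1 = c0[2L])
  }))
  structure(list(tip_scores = sc, node_scores = anc, edges = edges,
                 tree = tree, axes = axes,
                 proportion = space$proportion[axes]),
            class = "phylomorphospace")
}

#' @export
print.phylomorphospace <- function(x, ...) {
  cat("Phylomorphospace:", nrow(x$tip_scores), "tips,",
      nrow(x$node_scores), "internal nodes, axes",
      paste(x$axes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.phylomorphospace <- function(x, ...) {
  lab <- sprintf("PC%d (%.1f%%)", x$axes, 100 * x$proportion)
  rng <- apply(rbind(x$tip_scores, x$node_scores), 2L, range)
  graphics::plot(NA, xlim = rng[, 1L], ylim = rng[, 2L],
                 xlab = lab[1L], ylab = lab[2L], ...)
  graphics::segments(x$edges$x0, x$edges$y0, x$edges$x1, x$edges$y1,
                     col = "grey60")
  graphics::points(x$node_scores, pch = 21, bg = "grey", cex = 0.7)
  graphics::points(x$tip_scores, pch = 19)
  invisible(x)
}
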