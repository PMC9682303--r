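# Brownian-motion machinery shared by all phylogenetically corrected
# statistics: tree covariance, ancestral states, phylogenetic transformation
# and the multivariate phylogenetic signal Kmult.

#' Phylogenetic trait covariance implied by Brownian motion
#'
#' `C[i, j]` is the depth (root-to-node path length) of the most recent common
#' ancestor of tips i and j; the diagonal holds root-to-tip depths. Tip order
#' follows `tree$tip.label`.
#'
#' @param tree an [ape::phylo] with branch lengths
#' @return symmetric positive semi-definite matrix with tip-label dimnames
#' @export
phylo_vcv <- function(tree) {
  validate_tree(tree)
  C <- ape::vcv.phylo(tree)
  if (max(diag(C)) <= 0) stop("tree has zero depth")
  C[tree$tip.label, tree$tip.label]
}

# depths (root-to-node path lengths) for every node, root = 0
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

# inverse square root of a covariance matrix by eigendecomposition;
# eigenvalues floored at `floor` because trees with tiny terminal branches
# yield near-singular C
inv_sqrt_matrix <- function(C, floor = 1e-12) {
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

# GLS phylogenetic mean of a species x traits matrix given tree covariance C
phylo_mean <- function(Y, C) {
  w <- solve(C, rep(1, nrow(C)))
  drop(crossprod(Y, w)) / sum(w)
}

#' Ancestral state estimates under single-rate Brownian motion
#'
#' Generalized least squares / maximum likelihood estimates computed per
#' trait: the conditional expectation of each internal node given the tips,
#' using the full among-node Brownian covariance. The root estimate equals
#' the GLS phylogenetic mean used by [phylo_transform()].
#'
#' @param tree an [ape::phylo]
#' @param tip_values numeric matrix (species x traits) or named vector;
#'   rownames/names must cover all tips
#' @return matrix of internal-node estimates, rownames = node numbers
#'   (n_tips + 1 is the root)
#' @export
ancestral_states_bm <- function(tree, tip_values) {
  if (is.null(dim(tip_values))) {
    tip_values <- matrix(tip_values, ncol = 1L,
                         dimnames = list(names(tip_values), "trait"))
  }
  if (is.null(rownames(tip_values))) stop("tip values must be named by species")
  missing <- setdiff(tree$tip.label, rownames(tip_values))
  if (length(missing)) stop("missing tip values for: ",
                            paste(missing, collapse = ", "))
  Y <- tip_values[tree$tip.label, , drop = FALSE]
  n <- length(tree$tip.label)
  n_node <- tree$Nnode
  depth <- node_depths(tree)
  # shared path length between node u and tip i = depth of their MRCA
  mr <- ape::mrca(tree, full = TRUE)
  all_ids <- seq_len(n + n_node)
  Cfull <- matrix(depth[mr], n + n_node, n + n_node)
  Ctt <- Cfull[seq_len(n), seq_len(n)]
  internal <- (n + 1L):(n + n_node)
  Cut <- Cfull[internal, seq_len(n), drop = FALSE]
  a <- phylo_mean(Y, Ctt)
  resid <- sweep(Y, 2L, a)
  est <- Cut %*% solve(Ctt, resid)
  est <- sweep(est, 2L, a, `+`)
  rownames(est) <- as.character(internal)
  colnames(est) <- colnames(Y)
  est
}

#' Phylogenetic transformation of species trait data
#'
#' Returns `P^{-1/2} (Y - 1 a')` where `P^{-1/2}` is the inverse square root
#' of the tree covariance and `a` the GLS phylogenetic mean. Under single-rate
#' Brownian motion the transformed rows are uncorrelated, which is the
#' "phylogenetic correction" shared by the covariance-ratio, PLS, EMMLi and
#' rate analyses. The result is tagged and must not be transformed twice (the
#' operation is not idempotent).
#'
#' @param Y species x traits matrix; rownames must match `rownames(C)`
#' @param C tree covariance from [phylo_vcv()]
#' @return transformed matrix with attribute `phylo_transformed = TRUE`
#' @export
phylo_transform <- function(Y, C) {
  if (isTRUE(attr(Y, "phylo_transformed"))) {
    stop("data is already phylogenetically transformed; applying the ",
         "transform twice is not meaningful")
  }
  if (!is.null(rownames(Y)) && !is.null(rownames(C))) {
    if (!setequal(rownames(Y), rownames(C))) {
      stop("rownames of data and tree covariance do not match")
    }
    Y <- Y[rownames(C), , drop = FALSE]
  }
  if (nrow(Y) != nrow(C)) stop("data rows do not match tree covariance")
  a <- phylo_mean(Y, C)
  U <- inv_sqrt_matrix(C) %*% sweep(Y, 2L, a)
  rownames(U) <- rownames(C)
  colnames(U) <- colnames(Y)
  attr(U, "phylo_transformed") <- TRUE
  U
}

#' Multivariate phylogenetic signal (Kmult)
#'
#' Multivariate generalization of Blomberg's K: the ratio of the observed mean
#' squared Euclidean deviation of tips from the phylogenetic mean to its
#' phylogenetically corrected counterpart, scaled by the Brownian-motion
#' expectation of that ratio so that K is about 1 when shape evolves by
#' single-rate Brownian motion on the tree. K > 1 indicates stronger
#' resemblance among relatives than Brownian motion predicts. Significance by
#' permuting species' trait vectors across the tips.
#'
#' @param data species x traits matrix (e.g. flattened aligned shapes);
#'   rownames = species. A `species_shapes` object may be passed directly.
#' @param tree an [ape::phylo]; taxa must match the data
#' @param n_perm permutations for the p-value (default 1000)
#' @param seed optional integer seed for the permutations
#' @return object of class `"kmult"` with fields `K`, `p`, `n_perm`,
#'   `permuted` (null K values)
#' @export
kmult <- function(data, tree, n_perm = 1000L, seed = NULL) {
  Y <- as_species_matrix(data)
  if (nrow(Y) < 3L) stop("Kmult needs at least 3 species")
  missing <- setdiff(tree$tip.label, rownames(Y))
  if (length(missing)) stop("data missing species: ",
                            paste(missing, collapse = ", "))
  Y <- Y[tree$tip.label, , drop = FALSE]
  C <- phylo_vcv(tree)
  n <- nrow(C)
  Cinv1 <- solve(C, rep(1, n))
  expected <- (sum(diag(C)) - n / sum(Cinv1)) / (n - 1)
  Pinv_half <- inv_sqrt_matrix(C)
  k_stat <- function(Y) {
    a <- drop(crossprod(Y, Cinv1)) / sum(Cinv1)
    R <- sweep(Y, 2L, a)
    sse0 <- sum(R^2)
    if (sse0 == 0) stop("zero total variance in the data")
    sse <- sum((Pinv_half %*% R)^2)
    (sse0 / sse) / expected
  }
  obs <- k_stat(Y)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm),
                 function(i) k_stat(Y[sample.int(n), , drop = FALSE]),
                 numeric(1L))
  structure(list(K = obs, p = perm_pval(null, obs), n_perm = n_perm,
                 permuted = null, n_species = n),
            class = "kmult")
}

#' @export
print.kmult <- function(x, ...) {
  cat("Multivariate phylogenetic signal\n")
  cat(sprintf("  K = %.4f, p = %.4g (%d permutations, %d species)\n",
              x$K, x$p, x$n_perm, x$n_species))
  invisible(x)
}

#' Coerce shape containers to a species-by-traits matrix
#'
#' Flattens `species_shapes` objects, `k x d x n` arrays or plain matrices to
#' the species x (k*d) trait matrix (rownames = species, columns ordered
#' landmark-by-landmark) that the statistical functions operate on.
#'
#' @param data a `species_shapes`, a named `k x d x n` array, or a matrix
#' @return numeric matrix, species in rows
#' @export
as_species_matrix <- function(data) {
  if (inherits(data, "species_shapes")) return(flatten_shapes(data$coords))
  if (is.list(data) && !is.null(data$coords) && length(dim(data$coords)) == 3L) {
    return(flatten_shapes(data$coords))
  }
  if (length(dim(data)) == 3L) return(flatten_shapes(data))
  as.matrix(data)
}
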