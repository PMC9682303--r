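# Modularity and integration hypothesis tests: covariance ratio (global,
# pairwise, model comparison), phylogenetic two-block PLS, and EMMLi-style
# maximum-likelihood selection among modular hypotheses.

# expand a landmark partition into flattened-column index sets
partition_columns <- function(map, d) {
  lapply(module_indices(map), landmark_columns, d = d)
}

# CR for one module pair from a precomputed trait covariance matrix
cr_pair_from_cov <- function(S, cols1, cols2) {
  S12 <- S[cols1, cols2, drop = FALSE]
  S11 <- S[cols1, cols1, drop = FALSE]
  S22 <- S[cols2, cols2, drop = FALSE]
  diag(S11) <- 0
  diag(S22) <- 0
  denom <- sqrt(sum(S11^2) * sum(S22^2))
  if (denom == 0) stop("a module has no within-module covariance ",
                       "(single coordinate?)")
  sqrt(sum(S12^2) / denom)
}

# all pairwise CRs at once: aggregate squared covariances with a module
# indicator matrix (one matrix product per call, so permutation nulls with
# 1000 iterations stay cheap); g = module id per column, m = module count
cr_core <- function(S2, diag2, g, m) {
  p <- length(g)
  G <- matrix(0, p, m)
  G[cbind(seq_len(p), g)] <- 1
  A <- crossprod(G, S2 %*% G)          # block sums of squared covariances
  within <- diag(A) - drop(crossprod(G, diag2))
  if (any(within <= 0)) stop("a module has no within-module covariance ",
                             "(single coordinate?)")
  pairs <- utils::combn(m, 2L)
  vals <- sqrt(A[t(pairs)] / sqrt(within[pairs[1L, ]] * within[pairs[2L, ]]))
  list(cr = mean(vals), pairs = pairs, values = vals)
}

cr_from_cov <- function(S, col_sets) {
  g <- integer(ncol(S))
  for (j in seq_along(col_sets)) g[col_sets[[j]]] <- j
  cr_core(S * S, diag(S)^2, g, length(col_sets))
}

#' Covariance ratio between hypothesized modules
#'
#' For two modules with trait covariance blocks `S11`, `S22` (within) and
#' `S12` (between), `CR = sqrt(tr(S12 S21) / sqrt(tr(S11* S11*) tr(S22* S22*)))`
#' where `S*` is the within-module block with its diagonal zeroed. CR = 1
#' indicates no modular structure, lower values indicate greater modularity,
#' and values above 1 mean between-module covariance exceeds within-module
#' covariance. For more than two modules the statistic is the mean of all
#' pairwise CRs.
#'
#' @param data species x traits matrix of flattened shapes (or a
#'   `species_shapes` object); apply [phylo_transform()] first for the
#'   phylogenetically corrected version
#' @param partition a [module_map()] over the landmarks
#' @param d landmark dimensionality used to expand the partition to columns
#'   (inferred from a shape object, otherwise required when `ncol(data)` is a
#'   multiple of the landmark count; default 1 treats each column as its own
#'   "landmark")
#' @return scalar CR
#' @export
covariance_ratio <- function(data, partition, d = NULL) {
  Y <- as_species_matrix(data)
  if (is.null(d)) {
    d <- if (inherits(data, "species_shapes")) data$d else
      ncol(Y) / partition$k
  }
  if (d != round(d)) stop("column count is not a multiple of landmark count")
  cols <- partition_columns(partition, as.integer(d))
  if (length(cols) < 2L) stop("need at least 2 modules")
  if (any(lengths(cols) < 2L)) stop("every module needs at least 2 coordinates")
  S <- stats::cov(Y)
  cr_from_cov(S, cols)$cr
}

#' Permutation test of modularity via the covariance ratio
#'
#' If a tree is supplied the species data are phylogenetically transformed
#' first ([phylo_transform()]), giving the phylogenetically corrected CR. The
#' null distribution reassigns landmarks to modules at random (preserving
#' module sizes, the hypothesis under test being the partition); the p-value
#' is the proportion of null CRs at or below the observed value with the
#' (b+1)/(m+1) estimator, and the effect size is
#' `Z = (observed - mean(null)) / sd(null)` (more negative = more modular).
#'
#' @inheritParams covariance_ratio
#' @param tree optional [ape::phylo]; taxa must match the data rows
#' @param n_perm number of partition permutations (default 1000; fewer than
#'   100 triggers a warning)
#' @param seed optional integer seed
#' @return object of class `"cr_test"`: `cr`, `p`, `effect_size_z`,
#'   `pairwise` (module x module CR matrix), `null_distribution`
#' @export
modularity_test <- function(data, partition, tree = NULL, n_perm = 1000L,
                            d = NULL, seed = NULL) {
  Y <- as_species_matrix(data)
  if (is.null(d)) {
    d <- if (inherits(data, "species_shapes")) data$d else
      ncol(Y) / partition$k
  }
  d <- as.integer(d)
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse null distribution")
  if (!is.null(tree)) Y <- phylo_transform(Y, phylo_vcv(tree))
  S <- stats::cov(Y)
  cols <- partition_columns(partition, d)
  if (any(lengths(cols) < 2L)) stop("every module needs at least 2 coordinates")
  obs <- cr_from_cov(S, cols)
  m_names <- partition$module_names
  pw <- matrix(NA_real_, length(m_names), length(m_names),
               dimnames = list(m_names, m_names))
  for (j in seq_len(ncol(obs$pairs))) {
    a <- obs$pairs[1L, j]; b <- obs$pairs[2L, j]
    pw[a, b] <- pw[b, a] <- obs$values[j]
  }
  if (!is.null(seed)) set.seed(seed)
  S2 <- S * S; diag2 <- diag(S)^2
  g_lm <- match(partition$assignment, partition$module_names)
  m <- length(partition$module_names)
  null <- vapply(seq_len(n_perm), function(i) {
    cr_core(S2, diag2, rep(sample(g_lm), each = d), m)$cr
  }, numeric(1L))
  structure(list(cr = obs$cr, p = perm_pval(null, obs$cr, lower = TRUE),
                 effect_size_z = (obs$cr - mean(null)) / stats::sd(null),
                 pairwise = pw, null_distribution = null,
                 n_perm = n_perm, phylo = !is.null(tree)),
            class = "cr_test")
}

#' @export
print.cr_test <- function(x, ...) {
  cat(if (x$phylo) "Phylogenetically corrected covariance-ratio test\n"
      else "Covariance-ratio modularity test\n")
  cat(sprintf("  CR = %.4f, p = %.4g, Z = %.3f (%d permutations)\n",
              x$cr, x$p, x$effect_size_z, x$n_perm))
  invisible(x)
}

#' @export
summary.cr_test <- function(object, ...) {
  print(object)
  cat("  pairwise CR:\n")
  print(round(object$pairwise, 3))
  invisible(object)
}

#' Compare modular hypotheses by covariance-ratio effect size
#'
#' Each hypothesis with at least two modules gets a CR and a standardized
#' effect size Z against its own size-preserving landmark-permutation null;
#' the effect size is computed on log(CR), which stabilizes the variance of
#' the ratio statistic and makes effect sizes comparable across partitions
#' with different module counts. Models are ranked by Z (more negative =
#' stronger support for modularity).
#' A one-module hypothesis has no CR: it anchors the "no modularity" end of
#' the ranking and is reported with an empty statistic. Ties are reported,
#' not broken.
#'
#' @inheritParams modularity_test
#' @param hypotheses named list of [module_map()]s (see [module_battery()])
#' @return object of class `"cr_model_comparison"` with a `table` ranked by
#'   effect size
#' @export
compare_cr_models <- function(data, hypotheses, tree = NULL, n_perm = 1000L,
                              d = NULL, seed = NULL) {
  if (length(hypotheses) < 2L) stop("need at least 2 hypotheses")
  Y <- as_species_matrix(data)
  if (is.null(d)) {
    d <- if (inherits(data, "species_shapes")) data$d else
      ncol(Y) / hypotheses[[1L]]$k
  }
  d <- as.integer(d)
  if (!is.null(tree)) Y <- phylo_transform(Y, phylo_vcv(tree))
  S <- stats::cov(Y)
  S2 <- S * S; diag2 <- diag(S)^2
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(hypotheses), function(nm) {
    h <- hypotheses[[nm]]
    if (length(h$module_names) < 2L) {
      return(data.frame(model = nm, n_modules = 1L, cr = NA_real_,
                        z = NA_real_, p = NA_real_))
    }
    cols <- partition_columns(h, d)
    obs <- cr_from_cov(S, cols)$cr
    g_lm <- match(h$assignment, h$module_names)
    m <- length(h$module_names)
    null <- vapply(seq_len(n_perm), function(i) {
      cr_core(S2, diag2, rep(sample(g_lm), each = d), m)$cr
    }, numeric(1L))
    data.frame(model = nm, n_modules = length(h$module_names), cr = obs,
               z = (log(obs) - mean(log(null))) / stats::sd(log(null)),
               p = perm_pval(null, obs, lower = TRUE))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$z, na.last = TRUE), ]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 best = tab$model[which.min(tab$z)],
                 n_perm = n_perm, phylo = !is.null(tree)),
            class = "cr_model_comparison")
}

#' @export
print.cr_model_comparison <- function(x, ...) {
  cat("Covariance-ratio model comparison (", nrow(x$table), " hypotheses, ",
      x$n_perm, " permutations each)\n", sep = "")
  print(transform(x$table, cr = round(cr, 4), z = round(z, 3)))
  cat("best supported:", x$best, "\n")
  invisible(x)
}

#' Phylogenetic two-block partial least squares integration test
#'
#' For each module pair the (optionally phylogenetically transformed) data are
#' split into blocks and the between-block covariance is decomposed by
#' singular value decomposition; rPLS is the absolute correlation of the first
#' pair of singular-variate scores. rPLS near 0 means no integration between
#' the modules, near 1 full integration. The overall statistic is the mean
#' pairwise rPLS; the null permutes the species rows of one block, p-values by
#' the (b+1)/(m+1) estimator.
#'
#' @inheritParams modularity_test
#' @return object of class `"pls_test"`: `rpls` (overall), `p`,
#'   `pairwise_rpls` and `pairwise_p` matrices, `pairwise_p_bh`
#'   (Benjamini-Hochberg adjusted, informational only), per-pair singular
#'   vectors in `vectors`
#' @export
integration_test <- function(data, partition, tree = NULL, n_perm = 1000L,
                             d = NULL, seed = NULL) {
  Y <- as_species_matrix(data)
  if (is.null(d)) {
    d <- if (inherits(data, "species_shapes")) data$d else
      ncol(Y) / partition$k
  }
  d <- as.integer(d)
  if (!is.null(tree)) Y <- phylo_transform(Y, phylo_vcv(tree))
  Y <- sweep(Y, 2L, colMeans(Y))
  cols <- partition_columns(partition, d)
  if (length(cols) < 2L) stop("need at least 2 modules")
  m_names <- partition$module_names
  for (m in m_names) {
    if (sum(Y[, cols[[m]]]^2) == 0) {
      stop("module ", m, " has zero variance (rank-deficient block)")
    }
  }
  n <- nrow(Y)
  rpls_pair <- function(Y1, Y2) {
    s <- svd(crossprod(Y1, Y2) / (n - 1), nu = 1L, nv = 1L)
    s1 <- drop(Y1 %*% s$u); s2 <- drop(Y2 %*% s$v)
    list(r = abs(stats::cor(s1, s2)), u = s$u, v = s$v)
  }
  pairs <- utils::combn(length(cols), 2L)
  pw_r <- pw_p <- matrix(NA_real_, length(cols), length(cols),
                         dimnames = list(m_names, m_names))
  vectors <- list()
  if (!is.null(seed)) set.seed(seed)
  perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
  null_overall <- numeric(n_perm)
  obs_vals <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    Y1 <- Y[, cols[[a]], drop = FALSE]; Y2 <- Y[, cols[[b]], drop = FALSE]
    obs <- rpls_pair(Y1, Y2)
    obs_vals[j] <- obs$r
    vectors[[paste(m_names[a], m_names[b], sep = "-")]] <-
      list(u = obs$u, v = obs$v)
    null_j <- vapply(perms, function(pp) rpls_pair(Y1, Y2[pp, , drop = FALSE])$r,
                     numeric(1L))
    null_overall <- null_overall + null_j / ncol(pairs)
    pw_r[a, b] <- pw_r[b, a] <- obs$r
    pw_p[a, b] <- pw_p[b, a] <- perm_pval(null_j, obs$r)
  }
  overall <- mean(obs_vals)
  pbh <- pw_p
  pbh[upper.tri(pbh)] <- stats::p.adjust(pw_p[upper.tri(pw_p)], "BH")
  pbh[lower.tri(pbh)] <- t(pbh)[lower.tri(pbh)]
  structure(list(rpls = overall, p = perm_pval(null_overall, overall),
                 pairwise_rpls = pw_r, pairwise_p = pw_p,
                 pairwise_p_bh = pbh, vectors = vectors,
                 n_perm = n_perm, phylo = !is.null(tree)),
            class = "pls_test")
}

#' @export
print.pls_test <- function(x, ...) {
  cat(if (x$phylo) "Phylogenetic two-block PLS integration test\n"
      else "Two-block PLS integration test\n")
  cat(sprintf("  overall r-PLS = %.4f, p = %.4g (%d permutations)\n",
              x$rpls, x$p, x$n_perm))
  invisible(x)
}

#' @export
summary.pls_test <- function(object, ...) {
  print(object)
  cat("  pairwise r-PLS:\n"); print(round(object$pairwise_rpls, 3))
  cat("  pairwise p:\n"); print(round(object$pairwise_p, 4))
  invisible(object)
}
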