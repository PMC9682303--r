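# Generalized least-squares Procrustes superimposition and shape distances.

# optimal rotation (no reflection) aligning X onto Y, both centered
optimal_rotation <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    # flip the smallest singular direction to stay in SO(d)
    d <- ncol(R)
    s$u[, d] <- -s$u[, d]
    R <- s$u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes alignment of landmark configurations
#'
#' Removes translation (centroids to the origin), size (unit centroid size)
#' and orientation (least-squares rotation to an iteratively updated
#' consensus). Rotations are proper (determinant +1): biological specimens
#' have handedness, so reflections are never used. On convergence the
#' consensus is rotated to its principal axes (with a deterministic sign
#' convention) so output orientation is reproducible.
#'
#' @param shapes a [landmark_set()], or a `k x d x n` array
#' @param max_iter maximum consensus updates
#' @param tol convergence tolerance on the root-mean-square change of the
#'   consensus between iterations
#' @param project if `TRUE`, orthogonally project aligned shapes to the
#'   tangent space at the consensus (off by default; downstream Euclidean
#'   operations assume small shape variation either way)
#' @return object of class `"gpa_fit"`: `coords` (aligned `k x d x n` array),
#'   `centroid_size` (named, original units), `consensus` (`k x d`),
#'   `species`, `iterations`, `rss` (sum of squared deviations from the
#'   consensus at each iteration)
#' @export
gpa_align <- function(shapes, max_iter = 100L, tol = 1e-10, project = FALSE) {
  if (inherits(shapes, "landmark_set")) {
    arr <- shapes$coords; species <- shapes$species
  } else {
    arr <- shapes
    species <- dimnames(arr)[[3L]]
  }
  k <- dim(arr)[1L]; d <- dim(arr)[2L]; n <- dim(arr)[3L]
  ids <- dimnames(arr)[[3L]]
  if (is.null(ids)) ids <- paste0("config_", seq_len(n))
  cs <- numeric(n)
  aligned <- array(NA_real_, dim(arr), dimnames = dimnames(arr))
  for (i in seq_len(n)) {
    m <- center_config(arr[, , i])
    csi <- sqrt(sum(m^2))
    if (csi < .Machine$double.eps * k) {
      stop("zero centroid size (all landmarks coincident) in specimen ", ids[i])
    }
    cs[i] <- csi
    aligned[, , i] <- m / csi
  }
  names(cs) <- ids

  consensus <- aligned[, , 1L]
  rss_path <- numeric(0)
  iter <- 0L
  if (n > 1L) {
    repeat {
      iter <- iter + 1L
      for (i in seq_len(n)) {
        aligned[, , i] <- aligned[, , i] %*%
          optimal_rotation(aligned[, , i], consensus)
      }
      new_consensus <- apply(aligned, c(1L, 2L), mean)
      new_consensus <- new_consensus / sqrt(sum(center_config(new_consensus)^2))
      rss_path <- c(rss_path,
                    sum(sweep(aligned, c(1L, 2L), new_consensus)^2))
      delta <- sqrt(mean((new_consensus - consensus)^2))
      consensus <- new_consensus
      if (delta < tol || iter >= max_iter) break
    }
  } else {
    consensus <- aligned[, , 1L]
    iter <- 1L
    rss_path <- 0
  }

  # reproducible orientation: rotate to the consensus principal axes, then
  # fix signs from the consensus itself (largest-|coordinate| positive on the
  # first d-1 axes; the last sign keeps det = +1 so handedness is preserved)
  pc <- eigen(crossprod(center_config(consensus)), symmetric = TRUE)$vectors
  if (det(pc) < 0) pc[, d] <- -pc[, d]
  rotated <- consensus %*% pc
  signs <- rep(1, d)
  for (j in seq_len(d - 1L)) {
    signs[j] <- sign(rotated[which.max(abs(rotated[, j])), j])
  }
  signs[d] <- prod(signs[seq_len(d - 1L)])
  pc <- pc %*% diag(signs, d)
  consensus <- consensus %*% pc
  for (i in seq_len(n)) aligned[, , i] <- aligned[, , i] %*% pc

  if (project) {
    flat <- flatten_shapes(aligned)
    cvec <- as.vector(t(consensus))
    cvec <- cvec / sqrt(sum(cvec^2))
    dev <- sweep(flat, 2L, as.vector(t(consensus)))
    dev <- dev - outer(drop(dev %*% cvec), cvec)
    aligned <- unflatten_shapes(sweep(dev, 2L, as.vector(t(consensus)), `+`),
                                k, d)
    dimnames(aligned) <- list(NULL, c("x", "y", "z")[seq_len(d)], ids)
  }

  structure(list(coords = aligned, centroid_size = cs, consensus = consensus,
                 species = species, iterations = iter, rss = rss_path,
                 k = k, d = d, n = n, projected = project),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("Generalized Procrustes alignment\n")
  cat("  ", x$n, " configurations, ", x$k, " landmarks, ", x$d, "D\n", sep = "")
  cat("  converged after", x$iterations, "iteration(s); final RSS",
      format(utils::tail(x$rss, 1L), digits = 6), "\n")
  invisible(x)
}

#' @export
summary.gpa_fit <- function(object, ...) {
  cat("Generalized Procrustes alignment\n")
  cat("  configurations:", object$n, " landmarks:", object$k,
      " dimensions:", object$d, "\n")
  cat("  centroid size: ", paste(format(range(object$centroid_size), digits = 4),
                                 collapse = " - "), "\n")
  if (!is.null(object$species)) {
    cat("  species:", length(unique(object$species)), "\n")
  }
  invisible(object)
}

#' Species mean shapes from a joint Procrustes alignment
#'
#' Averages the aligned coordinates of each species' specimens (single joint
#' superimposition over all specimens; per-species alignments are never run).
#' Means are re-centered but not re-superimposed: means of aligned data are
#' already centered to within numerical error. Species are returned in sorted
#' order.
#'
#' @param fit a `gpa_fit` with species labels
#' @return object of class `"species_shapes"`: `coords` (`k x d x n_species`
#'   array, dimnames = species), `centroid_size` (mean per species),
#'   `consensus`
#' @export
species_mean_shapes <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  if (is.null(fit$species)) stop("no species labels in the alignment")
  sp <- sort(unique(fit$species))
  out <- array(NA_real_, c(fit$k, fit$d, length(sp)),
               dimnames = list(NULL, dimnames(fit$coords)[[2L]], sp))
  cs <- stats::setNames(numeric(length(sp)), sp)
  for (s in sp) {
    idx <- which(fit$species == s)
    m <- apply(fit$coords[, , idx, drop = FALSE], c(1L, 2L), mean)
    out[, , s] <- center_config(m)
    cs[s] <- mean(fit$centroid_size[idx])
  }
  structure(list(coords = out, centroid_size = cs, consensus = fit$consensus,
                 species = sp, k = fit$k, d = fit$d, n = length(sp)),
            class = "species_shapes")
}

#' @export
print.species_shapes <- function(x, ...) {
  cat("Species mean shapes:", x$n, "species,", x$k, "landmarks,",
      paste0(x$d, "D\n"))
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' Root of the minimized sum of squared differences after centering, scaling
#' to unit centroid size and optimal proper rotation (partial Procrustes
#' distance between unit-size configurations). Symmetric; zero iff the shapes
#' are identical up to a similarity transform.
#'
#' @param a,b `k x d` matrices with identical dimensions
#' @return non-negative scalar
#' @export
procrustes_distance <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- center_config(a); b <- center_config(b)
  ca <- sqrt(sum(a^2)); cb <- sqrt(sum(b^2))
  if (ca == 0 || cb == 0) stop("degenerate configuration with zero centroid size")
  a <- a / ca; b <- b / cb
  R <- optimal_rotation(a, b)
  sqrt(sum((a %*% R - b)^2))
}
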