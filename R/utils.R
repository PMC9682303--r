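# internal helpers shared across modules

#' Flatten a k x d x n landmark array to an n x (k*d) matrix
#'
#' Columns are ordered landmark-by-landmark (x1, y1, [z1], x2, ...) so that the
#' d coordinates of landmark j occupy columns (j-1)*d + 1:d. All module-aware
#' code relies on this layout.
#' @param a numeric array, k x d x n
#' @return n x (k*d) matrix, rownames taken from the third dimnames
#' @keywords internal
flatten_shapes <- function(a) {
  stopifnot(length(dim(a)) == 3L)
  k <- dim(a)[1L]; d <- dim(a)[2L]; n <- dim(a)[3L]
  out <- t(apply(a, 3L, function(m) as.vector(t(m))))
  if (n == 1L) out <- matrix(out, nrow = 1L)
  rownames(out) <- dimnames(a)[[3L]]
  colnames(out) <- paste0(rep(paste0("lm", seq_len(k)), each = d),
                          rep(c("x", "y", "z")[seq_len(d)], times = k))
  out
}

#' Restore a flattened shape vector/matrix to k x d configurations
#' @keywords internal
unflatten_shapes <- function(m, k, d) {
  if (is.null(dim(m))) {
    matrix(m, nrow = k, ncol = d, byrow = TRUE)
  } else {
    a <- array(NA_real_, c(k, d, nrow(m)), dimnames = list(NULL, NULL, rownames(m)))
    for (i in seq_len(nrow(m))) a[, , i] <- matrix(m[i, ], nrow = k, byrow = TRUE)
    a
  }
}

#' Column indices in a flattened shape matrix for a set of landmarks
#' @keywords internal
landmark_columns <- function(landmarks, d) {
  as.vector(vapply(landmarks, function(j) (j - 1L) * d + seq_len(d),
                   integer(d)))
}

#' Centroid size of one configuration
#' @keywords internal
centroid_size <- function(m) {
  cm <- colMeans(m)
  sqrt(sum(sweep(m, 2L, cm)^2))
}

#' Center a configuration at the origin
#' @keywords internal
center_config <- function(m) sweep(m, 2L, colMeans(m))

#' Permutation p-value, (b + 1) / (m + 1) estimator
#' @keywords internal
perm_pval <- function(null, obs, lower = FALSE) {
  b <- if (lower) sum(null <= obs) else sum(null >= obs)
  (b + 1) / (length(null) + 1)
}

# normalize taxon labels for matching only (original labels are preserved)
normalize_taxon <- function(x) gsub("[ ]+", "_", trimws(x))
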