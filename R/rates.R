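# Per-module evolutionary rate comparison and per-branch multirate Brownian
# motion by penalized likelihood.

#' Evolutionary rate ratio test among modules
#'
#' The multivariate Brownian rate of module m is estimated as
#' `sigma2_m = sum(U[, cols_m]^2) / (n_species * p_m)` where U is the
#' phylogenetically transformed data and p_m the number of coordinates in the
#' module; the observed statistic is the max/min rate ratio. The null
#' distribution replicates datasets along the phylogeny under single-rate
#' Brownian motion: one common per-trait rate (the pooled estimate) with the
#' observed trait correlations preserved, so correlated coordinates do not
#' inflate the test.
#'
#' @inheritParams modularity_test
#' @param tree an [ape::phylo]; required (rates are per unit branch length)
#' @param n_sim number of Brownian-motion simulations for the null
#' @param seed optional integer seed
#' @return object of class `"rate_ratio_test"`: `sigma2_per_module`, `ratio`,
#'   `p`, `null_distribution`
#' @export
module_rate_ratio_test <- function(data, partition, tree, n_sim = 1000L,
                                   d = NULL, seed = NULL) {
  Y <- as_species_matrix(data)
  if (is.null(d)) {
    d <- if (inherits(data, "species_shapes")) data$d else
      ncol(Y) / partition$k
  }
  d <- as.integer(d)
  cols <- partition_columns(partition, d)
  if (any(lengths(cols) == 0L)) stop("a module has no coordinates")
  C <- phylo_vcv(tree)
  Y <- Y[rownames(C), , drop = FALSE]
  n <- nrow(C); p <- ncol(Y)
  Pinv_half <- inv_sqrt_matrix(C)
  transform_resid <- function(Y) {
    a <- phylo_mean(Y, C)
    Pinv_half %*% sweep(Y, 2L, a)
  }
  rates_of <- function(U) {
    vapply(cols, function(cl) sum(U[, cl, drop = FALSE]^2) / (n * length(cl)),
           numeric(1L))
  }
  U <- transform_resid(Y)
  sig <- rates_of(U)
  obs <- max(sig) / min(sig)
  # null: single-rate BM with the pooled per-trait rate and the observed
  # trait correlation structure
  pooled <- sum(U^2) / (n * p)
  Rcor <- stats::cov2cor(crossprod(U) / (n - 1))
  er <- eigen(Rcor * pooled, symmetric = TRUE)
  Lr <- er$vectors %*% diag(sqrt(pmax(er$values, 0)), p)
  Lc <- t(chol(C))
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_sim), function(i) {
    Z <- matrix(stats::rnorm(n * p), n, p)
    Ysim <- Lc %*% Z %*% t(Lr)
    rownames(Ysim) <- rownames(C)
    r <- rates_of(transform_resid(Ysim))
    max(r) / min(r)
  }, numeric(1L))
  structure(list(sigma2_per_module = sig, ratio = obs,
                 p = perm_pval(null, obs), null_distribution = null,
                 n_sim = n_sim),
            class = "rate_ratio_test")
}

#' @export
print.rate_ratio_test <- function(x, ...) {
  cat("Evolutionary rate ratio test among modules\n")
  cat("  per-module sigma^2:\n")
  print(signif(x$sigma2_per_module, 4))
  cat(sprintf("  max/min ratio = %.3f, p = %.4g (%d simulations)\n",
              x$ratio, x$p, x$n_sim))
  invisible(x)
}

# edge x tip descendant incidence (TRUE where the tip lies below the edge)
edge_tip_incidence <- function(tree) {
  n <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  inc <- matrix(FALSE, n_edge, n)
  # postorder accumulation of descendant tip sets
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(ord))) {
    p <- ord[r, 1L]; ch <- ord[r, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  for (e in seq_len(n_edge)) inc[e, desc[[tree$edge[e, 2L]]]] <- TRUE
  inc
}

#' Multirate Brownian motion by penalized likelihood
#'
#' Fits branch-specific Brownian rates to a single continuous trait by
#' maximizing the trait log-likelihood plus lambda times the log probability
#' density of the log-rates themselves evolving by Brownian motion on the
#' tree. Rates are parametrized on the log scale at every node and tip; the
#' rate of an edge is `exp((v_parent + v_child)/2)`. Optimization is
#' quasi-Newton (BFGS) with numerical gradients, started from the single-rate
#' maximum-likelihood estimate, so the fit is deterministic given the data.
#' Large lambda shrinks all branch rates to the common single-rate estimate.
#'
#' @param trait named numeric vector, one value per tip
#' @param tree an [ape::phylo]
#' @param lambda smoothing coefficient (> 0; default 1, an intermediate
#'   penalty)
#' @param maxit,tol optimizer iteration cap and relative tolerance
#' @return object of class `"multirate_bm"`: `log_rates` (per node, tips
#'   first), `edge_rates`, `objective`, `logL`, `penalty`, `convergence`,
#'   `sig2_single` (the single-rate start)
#' @export
multirate_bm <- function(trait, tree, lambda = 1, maxit = 500L, tol = 1e-8) {
  if (lambda <= 0) stop("lambda must be positive")
  if (anyNA(trait) || any(!is.finite(trait))) stop("trait values must be finite")
  validate_tree(tree)
  y <- trait[tree$tip.label]
  if (anyNA(y)) stop("trait is missing values for some tips")
  n <- length(y)
  n_nodes <- n + tree$Nnode
  inc <- edge_tip_incidence(tree)
  bl <- tree$edge.length
  parent <- tree$edge[, 1L]; child <- tree$edge[, 2L]

  tip_cov <- function(edge_rates) {
    Cs <- matrix(0, n, n)
    for (e in seq_along(bl)) {
      tips <- which(inc[e, ])
      Cs[tips, tips] <- Cs[tips, tips] + bl[e] * edge_rates[e]
    }
    Cs
  }
  loglik <- function(edge_rates) {
    Cs <- tip_cov(edge_rates)
    ch <- tryCatch(chol(Cs), error = function(e) NULL)
    if (is.null(ch)) return(-1e10)
    one <- rep(1, n)
    Ci1 <- backsolve(ch, forwardsolve(t(ch), one))
    theta <- sum(Ci1 * y) / sum(Ci1)
    r <- y - theta
    Cir <- backsolve(ch, forwardsolve(t(ch), r))
    -0.5 * (sum(r * Cir) + 2 * sum(log(diag(ch))) + n * log(2 * pi))
  }
  # single-rate start
  C1 <- tip_cov(rep(1, length(bl)))
  ch1 <- chol(C1)
  one <- rep(1, n)
  Ci1 <- backsolve(ch1, forwardsolve(t(ch1), one))
  theta0 <- sum(Ci1 * y) / sum(Ci1)
  r0 <- y - theta0
  sig2_single <- sum(r0 * backsolve(ch1, forwardsolve(t(ch1), r0))) / n
  sig2_single <- max(sig2_single, 1e-12)

  objective <- function(v) {
    er <- exp((v[parent] + v[child]) / 2)
    pen <- -0.5 * lambda * sum((v[child] - v[parent])^2 / bl)
    -(loglik(er) + pen)
  }
  fit <- stats::optim(rep(log(sig2_single), n_nodes), objective,
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = tol))
  if (fit$convergence != 0 && fit$convergence != 1) {
    stop("multirate BM optimizer failed (code ", fit$convergence,
         "), last objective ", format(fit$value))
  }
  v <- fit$par
  er <- exp((v[parent] + v[child]) / 2)
  pen <- -0.5 * lambda * sum((v[child] - v[parent])^2 / bl)
  ll <- loglik(er)
  names(v) <- c(tree$tip.label, paste0("node", (n + 1L):n_nodes))
  structure(list(log_rates = v, edge_rates = er, objective = -fit$value,
                 logL = ll, penalty = pen, lambda = lambda,
                 convergence = fit$convergence, sig2_single = sig2_single,
                 tree = tree),
            class = "multirate_bm")
}

#' @export
print.multirate_bm <- function(x, ...) {
  cat("Multirate Brownian motion (penalized likelihood, lambda =",
      x$lambda, ")\n")
  cat(sprintf("  logL = %.4f, penalty = %.4f, objective = %.4f\n",
              x$logL, x$penalty, x$objective))
  cat(sprintf("  edge rates: %.4g - %.4g (single-rate start %.4g)\n",
              min(x$edge_rates), max(x$edge_rates), x$sig2_single))
  invisible(x)
}

#' Export per-branch rates as an edge table
#' @param x a `multirate_bm` fit
#' @return data frame with parent, child, branch length and fitted rate
#' @export
edge_rate_table <- function(x) {
  stopifnot(inherits(x, "multirate_bm"))
  data.frame(parent = x$tree$edge[, 1L], child = x$tree$edge[, 2L],
             length = x$tree$edge.length, rate = x$edge_rates)
}
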