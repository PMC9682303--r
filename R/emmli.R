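# EMMLi-style maximum-likelihood evaluation of modular hypotheses, plus the
# built-in hypothesis battery.

#' Congruence-coefficient correlation matrix between landmarks
#'
#' For landmarks i and j with per-species deviation vectors (d-dimensional,
#' deviations from the mean configuration), the congruence coefficient is the
#' inner-product correlation
#' `r_ij = sum_s <v_is, v_js> / sqrt(sum_s |v_is|^2 sum_s |v_js|^2)`.
#' This is the standard landmark-level association measure for configurations
#' where each landmark is a d-vector.
#'
#' @param data species x (k*d) flattened shapes, `species_shapes`, or a
#'   `k x d x n` array
#' @param d landmark dimensionality (inferred from shape objects)
#' @return k x k symmetric matrix with unit diagonal
#' @export
landmark_congruence <- function(data, d = NULL) {
  Y <- as_species_matrix(data)
  if (is.null(d)) {
    if (inherits(data, "species_shapes")) d <- data$d
    else if (length(dim(data)) == 3L) d <- dim(data)[2L]
    else stop("d must be given for plain matrices")
  }
  d <- as.integer(d)
  k <- ncol(Y) / d
  if (k != round(k)) stop("column count is not a multiple of d")
  k <- as.integer(k)
  Yc <- sweep(Y, 2L, colMeans(Y))
  R <- matrix(NA_real_, k, k)
  norms <- numeric(k)
  blocks <- lapply(seq_len(k), function(j) Yc[, (j - 1L) * d + seq_len(d),
                                              drop = FALSE])
  for (j in seq_len(k)) norms[j] <- sum(blocks[[j]]^2)
  for (i in seq_len(k)) {
    R[i, i] <- 1
    for (j in seq_len(k)[-seq_len(i)]) {
      R[i, j] <- R[j, i] <- sum(blocks[[i]] * blocks[[j]]) /
        sqrt(norms[i] * norms[j])
    }
  }
  R
}

# small-sample Akaike information criterion on n data points
emmli_aicc <- function(logL, K, n) {
  2 * K - 2 * logL + (2 * K * (K + 1)) / (n - K - 1)
}

# pair sets (within per module, between per module pair) for one hypothesis
emmli_pair_sets <- function(map) {
  k <- map$k
  idx <- module_indices(map)
  m <- map$module_names
  sets <- list()
  for (a in m) {
    pairs <- if (length(idx[[a]]) >= 2L) utils::combn(idx[[a]], 2L) else NULL
    if (!is.null(pairs)) sets[[paste0("within.", a)]] <- pairs
  }
  if (length(m) >= 2L) {
    for (i in seq_len(length(m) - 1L)) for (j in (i + 1L):length(m)) {
      pairs <- as.matrix(expand.grid(idx[[m[i]]], idx[[m[j]]]))
      sets[[paste0("between.", m[i], ".", m[j])]] <- t(pairs)
    }
  }
  sets
}

#' Likelihood-based comparison of modular hypotheses (EMMLi)
#'
#' Builds the landmark congruence-coefficient matrix and, under each
#' hypothesis, pools the unique landmark-pair correlations into one rho per
#' within-module set and one per between-module pair. Correlations are
#' modelled on the Fisher-z scale as Normal(z(rho), 1/(n-3)) with n the
#' number of species; the pooled rho maximizing the likelihood of a set is the
#' back-transformed mean z. Models are compared by AICc with
#' K = number of distinct rho parameters + 1 and the number of unique
#' landmark-pair correlations (the data points entering the likelihood) as
#' the AICc sample size, which is what lets the method favour richly
#' parametrized models when the data support them. Akaike weights come from
#' delta-AICc; models with more parameters than the pair count supports
#' (pairs <= K + 1) are flagged unfit and excluded from the weights.
#'
#' @param data aligned species mean shapes (`species_shapes`, array, or
#'   species x (k*d) matrix). Apply [phylo_transform()] first for the
#'   phylogenetically corrected analysis.
#' @param hypotheses named list of [module_map()]s
#' @param sample_size number of species (defaults to `nrow(data)`)
#' @param d landmark dimensionality for plain matrices
#' @return object of class `"emmli_fit"`: `table` (model, logL, K, AICc,
#'   dAICc, weight, unfit), `best`, `rho_within` (named vector for the best
#'   model), `rho_between` (module x module matrix for the best model),
#'   `congruence`
#' @export
emmli_fit <- function(data, hypotheses, sample_size = NULL, d = NULL) {
  if (length(hypotheses) < 2L) stop("need at least 2 hypotheses")
  Y <- as_species_matrix(data)
  if (is.null(sample_size)) sample_size <- nrow(Y)
  if (sample_size <= 4L) stop("sample size too small for the Fisher-z model")
  R <- landmark_congruence(data, d = d)
  z <- atanh(pmin(pmax(R, -0.999999), 0.999999))
  sdz <- 1 / sqrt(sample_size - 3)
  n_pairs <- nrow(R) * (nrow(R) - 1L) / 2L
  fit_one <- function(map) {
    sets <- emmli_pair_sets(map)
    logL <- 0
    rho <- stats::setNames(numeric(length(sets)), names(sets))
    for (s in names(sets)) {
      pr <- sets[[s]]
      zv <- z[cbind(pr[1L, ], pr[2L, ])]
      zbar <- mean(zv)
      rho[s] <- tanh(zbar)
      logL <- logL + sum(stats::dnorm(zv, zbar, sdz, log = TRUE))
    }
    K <- length(sets) + 1L
    unfit <- n_pairs <= K + 1L
    aicc <- if (unfit) NA_real_ else emmli_aicc(logL, K, n_pairs)
    list(logL = logL, K = K, AICc = aicc, rho = rho, unfit = unfit)
  }
  fits <- lapply(hypotheses, fit_one)
  tab <- data.frame(model = names(hypotheses),
                    n_modules = vapply(hypotheses,
                                       function(h) length(h$module_names), 1L),
                    logL = vapply(fits, `[[`, numeric(1L), "logL"),
                    K = vapply(fits, `[[`, integer(1L), "K"),
                    AICc = vapply(fits, `[[`, numeric(1L), "AICc"),
                    unfit = vapply(fits, `[[`, logical(1L), "unfit"))
  ok <- !tab$unfit
  tab$dAICc <- tab$AICc - min(tab$AICc[ok])
  w <- exp(-tab$dAICc[ok] / 2)
  tab$weight <- NA_real_
  tab$weight[ok] <- w / sum(w)
  tab <- tab[order(tab$AICc), ]
  rownames(tab) <- NULL
  best <- tab$model[1L]
  best_map <- hypotheses[[best]]
  best_rho <- fits[[best]]$rho
  m <- best_map$module_names
  rho_b <- matrix(NA_real_, length(m), length(m), dimnames = list(m, m))
  rho_w <- stats::setNames(rep(NA_real_, length(m)), m)
  for (nm in names(best_rho)) {
    if (startsWith(nm, "within.")) {
      rho_w[sub("^within\\.", "", nm)] <- best_rho[nm]
    } else {
      parts <- strsplit(sub("^between\\.", "", nm), ".", fixed = TRUE)[[1L]]
      # module names themselves must not contain "."; enforced below
      rho_b[parts[1L], parts[2L]] <- rho_b[parts[2L], parts[1L]] <- best_rho[nm]
    }
  }
  structure(list(table = tab, best = best, rho_within = rho_w,
                 rho_between = rho_b, congruence = R,
                 sample_size = sample_size),
            class = "emmli_fit")
}

#' @export
print.emmli_fit <- function(x, ...) {
  cat("EMMLi modular hypothesis comparison (n =", x$sample_size, ")\n")
  tab <- x$table
  tab$logL <- round(tab$logL, 2); tab$AICc <- round(tab$AICc, 2)
  tab$dAICc <- round(tab$dAICc, 2); tab$weight <- round(tab$weight, 3)
  print(tab)
  cat("best supported:", x$best, "\n")
  invisible(x)
}

#' Built-in battery of modular hypotheses
#'
#' Ten a priori models ranging from fully integrated (one module) to seven
#' modules, built by merging a seven-module base partition. With the default
#' base map this mirrors the seven loricariid body regions (mouth,
#' neurocranium, opercula, pectoral+dorsal fins, pelvic fins, anal area,
#' caudal peduncle); the 2-module (head vs postcranium), 3-module
#' (head/midbody/tail) and 4-module (mouth | neurocranium+opercula |
#' paired+dorsal fins | anal+caudal) groupings are the biologically named
#' models. The intermediate models are documented interpolations that refine
#' the 4-module groupings one merger at a time (skull = neurocranium +
#' opercula, fins = pectoral/dorsal + pelvic, tail = anal + caudal), so the
#' battery forms a nested hierarchy between the named models (the original
#' study's full model list lives in its supplement; these reconstructions
#' preserve its 1-to-7-module range).
#'
#' @param base a seven-module [module_map()]; default [loricariid_module_map()]
#' @return named list of 10 `module_map`s
#' @export
module_battery <- function(base = loricariid_module_map()) {
  m <- base$module_names
  if (length(m) != 7L) stop("the battery is built from a seven-module base map")
  relabel <- function(groups, name) {
    lut <- stats::setNames(rep(names(groups), lengths(groups)),
                           unlist(groups))
    module_map(lut[base$assignment], names(groups))
  }
  g <- function(...) list(...)
  list(
    one_module = module_map(rep("all", base$k)),
    two_head_postcranium = relabel(g(head = m[1:3], postcranium = m[4:7])),
    two_mouth_rest = relabel(g(mouth = m[1L], rest = m[2:7])),
    three_head_midbody_tail = relabel(g(head = m[1:3], midbody = m[4:5],
                                        tail = m[6:7])),
    three_mouth_cranium_rest = relabel(g(mouth = m[1L], cranium = m[2:3],
                                         rest = m[4:7])),
    four_hypostominae = relabel(g(mouth = m[1L], cranium = m[2:3],
                                  fins = m[4:5], tail = m[6:7])),
    five_split_tail = relabel(stats::setNames(
      g(m[1L], m[2:3], m[4:5], m[6L], m[7L]),
      c("mouth", "skull", "fins", "anal", "caudal"))),
    five_split_fins = relabel(stats::setNames(
      g(m[1L], m[2:3], m[4L], m[5L], m[6:7]),
      c("mouth", "skull", "pect_dorsal", "pelvic", "tail"))),
    six_skull = relabel(stats::setNames(
      g(m[1L], m[2:3], m[4L], m[5L], m[6L], m[7L]),
      c("mouth", "skull", "pect_dorsal", "pelvic", "anal", "caudal"))),
    seven_modules = base
  )
}

#' Seven-region loricariid body module map (reconstruction)
#'
#' A 33-landmark, seven-module partition following the body regions used for
#' suckermouth armoured catfishes: mouth (6 landmarks: snout tip, lateral
#' mouth joints, lateral and posterior oral-disc points), neurocranium (10:
#' nares and four points around each eye), opercula (4), pectoral and dorsal
#' fins (5: pectoral origins/insertions and dorsal-fin origin), pelvic fins
#' (4), anal area (2: cloaca and anal-fin origin) and caudal peduncle (2).
#' The exact per-landmark indices of the original digitizing scheme are not
#' published in full; this map is a synthetic reconstruction with the correct
#' region structure and sizes, intended for simulated data and as a template
#' for real datasets (supply your own map via [read_module_map()]).
#'
#' @return a [module_map()] over 33 landmarks
#' @export
loricariid_module_map <- function() {
  module_map(rep(c("mouth", "neurocranium", "opercula", "pect_dorsal_fins",
                   "pelvic_fins", "anal_area", "caudal_peduncle"),
                 times = c(6L, 10L, 4L, 5L, 4L, 2L, 2L)))
}

#' Module-network summary of modularity/integration results
#'
#' Mirrors the network view of between-module relationships: nodes are
#' modules, edges carry the pairwise CR and r-PLS, and flags mark high
#' covariation (CR >= cr_cut) and high integration (rPLS >= rpls_cut).
#'
#' @param cr_test a [modularity_test()] result
#' @param pls_test an [integration_test()] result on the same partition
#' @param cr_cut,rpls_cut cut-offs for the "high" labels (defaults 1.00, 0.75)
#' @return list with `nodes` and `edges` data frames (JSON-ready)
#' @export
module_network <- function(cr_test, pls_test, cr_cut = 1.00, rpls_cut = 0.75) {
  m <- rownames(cr_test$pairwise)
  pairs <- utils::combn(m, 2L)
  edges <- data.frame(
    from = pairs[1L, ], to = pairs[2L, ],
    cr = cr_test$pairwise[t(pairs)],
    rpls = pls_test$pairwise_rpls[t(pairs)],
    p_rpls = pls_test$pairwise_p[t(pairs)])
  edges$high_covariation <- edges$cr >= cr_cut
  edges$high_integration <- edges$rpls >= rpls_cut
  list(nodes = data.frame(module = m), edges = edges)
}
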