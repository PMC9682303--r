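# Full-pipeline orchestration from a config file or list: alignment, means,
# ordination, phylogenetic signal, modularity/integration, rates, disparity
# and convergence, with deterministic seeding and per-subgroup reruns.

#' Run the full shape-modularity analysis pipeline
#'
#' Executes the complete analysis order: Procrustes alignment, species means,
#' PCA with broken-stick axis selection, phylomorphospace, Kmult, modularity
#' (covariance ratio) with model comparison, integration (PLS), EMMLi, rate
#' ratios, disparity through time (when the tree is ultrametric) and
#' convergence metrics (when focal taxa are configured). Subgroups with at
#' least 5 species are re-analysed separately using species means from the
#' single joint alignment; smaller subgroups are skipped with a logged
#' warning. All randomness flows from the single config seed through fixed
#' per-stage offsets.
#'
#' @param config path to a YAML file or a named list with fields:
#'   `landmarks` (path), `landmark_format` ("tps"/"table"), `tree` (path),
#'   `module_map` (path; optional, defaults to the battery base),
#'   `n_perm` (>= 100), `seed` (required), `out_dir`, and optionally
#'   `species_table`, `subgroups` (CSV with species, group), `focal_taxa`,
#'   `n_slices`, `n_sim_rates`, `n_sim_convergence`
#' @return invisibly, a list of the fitted result objects; result tables and
#'   a manifest are written under `out_dir`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config must declare a seed")
  n_perm <- config$n_perm %||% 1000L
  if (n_perm < 100L) stop("n_perm must be at least 100")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  logf <- file.path(out_dir, "run.log")
  log_msg <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }

  log_msg("reading inputs")
  lms <- read_landmarks(config$landmarks,
                        format = config$landmark_format %||% "tps",
                        species_table = config$species_table)
  tree <- read_shape_tree(config$tree)
  map <- if (!is.null(config$module_map)) read_module_map(config$module_map)
         else loricariid_module_map()
  if (map$k != lms$k) stop("module map covers ", map$k, " landmarks but data has ", lms$k)

  log_msg("Procrustes alignment of ", lms$n, " specimens")
  fit <- gpa_align(lms)
  means <- species_mean_shapes(fit)
  matched <- match_taxa(means, tree)
  if (length(matched$report$dropped_from_shapes) ||
      length(matched$report$dropped_from_tree)) {
    log_msg("dropped from shapes: ",
            paste(matched$report$dropped_from_shapes, collapse = ", "),
            "; from tree: ",
            paste(matched$report$dropped_from_tree, collapse = ", "))
  }
  arr <- matched$shapes
  tree <- matched$tree
  d <- dim(arr)[2L]

  analyse_group <- function(arr, tree, label, seed_base) {
    res <- list()
    flat <- flatten_shapes(arr)
    pca <- shape_pca(arr)
    res$pca <- pca
    res$n_signif <- broken_stick_axes(pca)
    res$kmult <- kmult(flat, tree, n_perm = n_perm, seed = seed_base + 1L)
    res$modularity <- modularity_test(flat, map, tree = tree, n_perm = n_perm,
                                      d = d, seed = seed_base + 2L)
    res$models <- compare_cr_models(flat, module_battery(map), tree = tree,
                                    n_perm = n_perm, d = d,
                                    seed = seed_base + 3L)
    res$integration <- integration_test(flat, map, tree = tree,
                                        n_perm = n_perm, d = d,
                                        seed = seed_base + 4L)
    res$emmli <- emmli_fit(phylo_transform(flat, phylo_vcv(tree)),
                           module_battery(map), sample_size = nrow(flat),
                           d = d)
    res$rates <- module_rate_ratio_test(flat, map, tree,
                                        n_sim = config$n_sim_rates %||% 1000L,
                                        d = d, seed = seed_base + 5L)
    if (ape::is.ultrametric(tree, tol = 1e-6)) {
      ax <- seq_len(max(res$n_signif, 2L))
      res$dtt <- disparity_through_time(pca$scores[, ax, drop = FALSE], tree,
                                        n_slices = config$n_slices %||% 31L,
                                        clade = label)
    } else log_msg(label, ": tree not ultrametric, skipping disparity profile")
    res
  }

  log_msg("analysing all species (n = ", dim(arr)[3L], ")")
  results <- list(all = analyse_group(arr, tree, "all", seed))

  # battery base needs 7 modules; phylomorphospace on the full group
  pms <- phylomorphospace(results$all$pca, tree)
  results$all$phylomorphospace <- pms

  if (!is.null(config$focal_taxa)) {
    ax <- seq_len(max(results$all$n_signif, 2L))
    results$all$convergence <- convergence_c_metrics(
      results$all$pca$scores[, ax, drop = FALSE], tree, config$focal_taxa,
      n_sim = config$n_sim_convergence %||% 100L, seed = seed + 6L)
    results$all$convnum <- convnum_ellipse(
      results$all$pca$scores[, 1:2], tree, config$focal_taxa)
  }

  if (!is.null(config$subgroups)) {
    sub <- utils::read.csv(config$subgroups, stringsAsFactors = FALSE)
    for (g in unique(sub$group)) {
      sp <- intersect(sub$species[sub$group == g], dimnames(arr)[[3L]])
      if (length(sp) < 5L) {
        log_msg("subgroup ", g, " has ", length(sp),
                " species (< 5), skipped")
        next
      }
      log_msg("analysing subgroup ", g, " (n = ", length(sp), ")")
      sub_tree <- ape::keep.tip(tree, sp)
      sub_arr <- arr[, , sub_tree$tip.label, drop = FALSE]
      results[[g]] <- analyse_group(sub_arr, sub_tree, g,
                                    seed + 100L * match(g, unique(sub$group)))
    }
  }

  log_msg("writing results to ", out_dir)
  write_results(results, out_dir)
  manifest <- list(seed = seed, n_perm = n_perm,
                   groups = names(results),
                   package_version = as.character(utils::packageVersion("morphmod")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_results <- function(results, out_dir) {
  for (g in names(results)) {
    r <- results[[g]]
    pre <- function(name) file.path(out_dir, paste0(g, "_", name))
    utils::write.csv(data.frame(species = rownames(r$pca$scores),
                                r$pca$scores),
                     pre("scores.csv"), row.names = FALSE)
    utils::write.csv(summary(r$pca), pre("eigenvalues.csv"), row.names = FALSE)
    utils::write.csv(data.frame(statistic = c("n_significant_axes", "K", "K_p"),
                                value = c(r$n_signif, r$kmult$K, r$kmult$p)),
                     pre("signal.csv"), row.names = FALSE)
    utils::write.csv(data.frame(module = rownames(r$modularity$pairwise),
                                r$modularity$pairwise),
                     pre("cr_pairwise.csv"), row.names = FALSE)
    utils::write.csv(r$models$table, pre("cr_models.csv"), row.names = FALSE)
    utils::write.csv(data.frame(module = rownames(r$integration$pairwise_rpls),
                                r$integration$pairwise_rpls),
                     pre("rpls_pairwise.csv"), row.names = FALSE)
    utils::write.csv(r$emmli$table, pre("emmli.csv"), row.names = FALSE)
    utils::write.csv(data.frame(module = names(r$rates$sigma2_per_module),
                                sigma2 = r$rates$sigma2_per_module,
                                ratio = r$rates$ratio, p = r$rates$p),
                     pre("rates.csv"), row.names = FALSE)
    if (!is.null(r$dtt)) {
      prof <- r$dtt$profile
      prof$burst <- c(FALSE, diff(prof$disparity) > r$dtt$burst_threshold)
      prof$clade <- g
      utils::write.csv(prof, pre("disparity.csv"), row.names = FALSE)
    }
    if (!is.null(r$convergence)) {
      utils::write.csv(data.frame(metric = names(r$convergence$observed),
                                  value = r$convergence$observed,
                                  p = r$convergence$p),
                       pre("convergence.csv"), row.names = FALSE)
    }
  }
}
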