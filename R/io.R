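# Landmark, tree and module-map input/output, plus taxon reconciliation.

#' Construct a landmark set
#'
#' A landmark set holds the raw digitized coordinates for a collection of
#' specimens: a `k x d x n` array (k landmarks, d = 2 or 3 dimensions,
#' n specimens) together with specimen identifiers and species labels.
#'
#' @param coords numeric array `k x d x n` (a `k x d` matrix is promoted to
#'   a single-specimen array)
#' @param specimen_id character vector of length n, unique specimen labels
#' @param species character vector of length n; if `NULL`, species are parsed
#'   from `specimen_id` with `species_pattern`
#' @param species_pattern regular expression with one capture group applied to
#'   specimen ids to extract the species label; the default takes everything
#'   before the last underscore
#' @return object of class `"landmark_set"`
#' @export
landmark_set <- function(coords, specimen_id, species = NULL,
                         species_pattern = "^(.*)_[^_]+$") {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L)
  k <- dim(coords)[1L]; d <- dim(coords)[2L]; n <- dim(coords)[3L]
  if (k < 3L) stop("at least 3 landmarks are required, got ", k)
  if (!d %in% c(2L, 3L)) stop("landmarks must be 2D or 3D, got d = ", d)
  if (length(specimen_id) != n) stop("specimen_id length does not match array")
  if (anyDuplicated(specimen_id)) stop("duplicate specimen ids")
  if (anyNA(coords)) {
    bad <- specimen_id[apply(coords, 3L, anyNA)]
    stop("missing coordinates in specimen(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(species)) {
    species <- sub(species_pattern, "\\1", specimen_id)
  }
  stopifnot(length(species) == n)
  dimnames(coords) <- list(NULL, c("x", "y", "z")[seq_len(d)], specimen_id)
  structure(list(coords = coords, specimen_id = as.character(specimen_id),
                 species = as.character(species), k = k, d = d, n = n),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("Landmark set:", x$n, "specimens,", length(unique(x$species)),
      "species,", x$k, "landmarks in", x$d, "dimensions\n")
  invisible(x)
}

#' Read landmark configurations from a TPS or wide-table file
#'
#' The TPS dialect accepted: `LM=k` or `LM3=k` headers, k coordinate lines of
#' 2 or 3 whitespace-separated numbers, an `ID=` line naming the specimen.
#' `SCALE=` and `IMAGE=` lines are ignored (superimposition removes scale
#' anyway). The table format is a CSV with one row per specimen, a `specimen`
#' column, an optional `species` column and coordinate columns
#' `x1,y1,[z1],x2,...`.
#'
#' @param path file to read
#' @param format `"tps"` or `"table"`
#' @param species_table optional data frame (or CSV path) with columns
#'   `specimen` and `species`, overriding species parsed from ids
#' @param species_pattern see [landmark_set()]
#' @return a `landmark_set`
#' @export
read_landmarks <- function(path, format = c("tps", "table"),
                           species_table = NULL,
                           species_pattern = "^(.*)_[^_]+$") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  out <- if (format == "tps") read_tps(path) else read_landmark_table(path)
  species <- NULL
  if (!is.null(species_table)) {
    if (is.character(species_table)) {
      species_table <- utils::read.csv(species_table, stringsAsFactors = FALSE)
    }
    idx <- match(out$ids, species_table$specimen)
    if (anyNA(idx)) stop("species table is missing specimen(s): ",
                         paste(out$ids[is.na(idx)], collapse = ", "))
    species <- species_table$species[idx]
  } else if (!is.null(out$species)) {
    species <- out$species
  }
  landmark_set(out$coords, out$ids, species = species,
               species_pattern = species_pattern)
}

read_tps <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  i <- 1L; n_lines <- length(lines)
  configs <- list(); ids <- character()
  while (i <= n_lines) {
    if (lines[i] == "") { i <- i + 1L; next }
    m <- regmatches(lines[i], regexec("^LM(3?)=([0-9]+)$", lines[i],
                                      ignore.case = TRUE))[[1L]]
    if (length(m) == 0L) stop("expected LM= header at line ", i, ": ", lines[i])
    d <- if (m[2L] == "3") 3L else 2L
    k <- as.integer(m[3L])
    coords <- matrix(NA_real_, k, d)
    for (j in seq_len(k)) {
      i <- i + 1L
      if (i > n_lines) stop("unexpected end of file inside specimen ",
                            length(configs) + 1L)
      vals <- suppressWarnings(as.numeric(strsplit(lines[i], "[ \t]+")[[1L]]))
      if (length(vals) != d || anyNA(vals)) {
        stop("non-numeric or malformed coordinate at line ", i, ": ", lines[i])
      }
      coords[j, ] <- vals
    }
    id <- paste0("specimen_", length(configs) + 1L)
    # trailing keyword lines until the next LM= header
    while (i + 1L <= n_lines && !grepl("^LM", lines[i + 1L], ignore.case = TRUE)) {
      i <- i + 1L
      if (grepl("^ID=", lines[i], ignore.case = TRUE)) {
        id <- sub("^ID=", "", lines[i], ignore.case = TRUE)
      }
      # SCALE=, IMAGE= and blank lines are ignored
    }
    configs[[length(configs) + 1L]] <- coords
    ids <- c(ids, id)
    i <- i + 1L
  }
  if (length(configs) == 0L) stop("no specimens found in ", path)
  ks <- vapply(configs, nrow, 1L); ds <- vapply(configs, ncol, 1L)
  if (length(unique(ks)) > 1L || length(unique(ds)) > 1L) {
    bad <- which(ks != ks[1L] | ds != ds[1L])[1L]
    stop("specimen ", bad, " (", ids[bad], ") has ", ks[bad], " landmarks in ",
         ds[bad], "D; specimen 1 has ", ks[1L], " in ", ds[1L], "D")
  }
  arr <- array(unlist(configs), c(ks[1L], ds[1L], length(configs)))
  # unlist concatenates column-major per matrix, which array() preserves
  list(coords = arr, ids = ids, species = NULL)
}

read_landmark_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"specimen" %in% names(df)) stop("table must have a 'specimen' column")
  species <- if ("species" %in% names(df)) df$species else NULL
  coord_cols <- grep("^[xyz][0-9]+$", names(df), value = TRUE)
  d <- if (any(grepl("^z", coord_cols))) 3L else 2L
  k <- length(coord_cols) / d
  if (k != round(k)) stop("coordinate columns do not form complete landmarks")
  k <- as.integer(k)
  ord <- paste0(rep(c("x", "y", "z")[seq_len(d)], times = k),
                rep(seq_len(k), each = d))
  if (!all(ord %in% names(df))) {
    stop("missing coordinate columns: ", paste(setdiff(ord, names(df)), collapse = ", "))
  }
  m <- as.matrix(df[, ord])
  if (!is.numeric(m)) stop("non-numeric coordinate values in ", path)
  arr <- array(NA_real_, c(k, d, nrow(df)))
  for (i in seq_len(nrow(df))) arr[, , i] <- matrix(m[i, ], k, d, byrow = TRUE)
  list(coords = arr, ids = df$specimen, species = species)
}

#' Write landmark configurations to TPS or wide-table format
#'
#' @param x a `landmark_set` (or a `k x d x n` array with dimnames)
#' @param path output file
#' @param format `"tps"` or `"table"`
#' @export
write_landmarks <- function(x, path, format = c("tps", "table")) {
  format <- match.arg(format)
  if (!inherits(x, "landmark_set")) stop("x must be a landmark_set")
  if (format == "tps") {
    con <- file(path, "w"); on.exit(close(con))
    hdr <- if (x$d == 3L) "LM3=" else "LM="
    for (i in seq_len(x$n)) {
      writeLines(paste0(hdr, x$k), con)
      writeLines(apply(x$coords[, , i, drop = FALSE], 1L,
                       function(r) paste(sprintf("%.17g", r), collapse = " ")),
                 con)
      writeLines(paste0("ID=", x$specimen_id[i]), con)
    }
  } else {
    flat <- flatten_shapes(x$coords)
    colnames(flat) <- paste0(rep(c("x", "y", "z")[seq_len(x$d)], times = x$k),
                             rep(seq_len(x$k), each = x$d))
    # full precision so write -> read round trips are exact
    txt <- apply(flat, 2L, function(col) sprintf("%.17g", col))
    df <- data.frame(specimen = x$specimen_id, species = x$species,
                     txt, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths from a Newick file or string
#'
#' Validates the invariants the downstream Brownian-motion machinery needs:
#' branch lengths present and non-negative, unique tip labels, rooted topology.
#' Polytomies are allowed.
#'
#' @param path path to a Newick file, or a Newick string
#' @return an [ape::phylo] object
#' @export
read_shape_tree <- function(path) {
  tree <- if (grepl(";", path, fixed = TRUE) && !file.exists(path)) {
    ape::read.tree(text = path)
  } else {
    ape::read.tree(path)
  }
  if (is.null(tree)) stop("could not parse Newick input")
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  # a root node must exist; basal polytomies (star trees) are acceptable
  if (is.null(tree$Nnode) || tree$Nnode < 1L) stop("tree has no root node")
  tree
}

#' Construct a module map: a partition of landmarks into named modules
#'
#' @param assignment vector of length k giving the module label of each
#'   landmark (character or factor)
#' @param module_names optional ordered module labels; defaults to order of
#'   first appearance
#' @return object of class `"module_map"`
#' @export
module_map <- function(assignment, module_names = NULL) {
  assignment <- as.character(assignment)
  if (anyNA(assignment)) stop("every landmark must be assigned to a module")
  if (is.null(module_names)) module_names <- unique(assignment)
  if (!setequal(module_names, unique(assignment))) {
    stop("module_names must match the labels used in the assignment")
  }
  if (any(table(assignment) == 0L)) stop("empty module in map")
  structure(list(assignment = assignment,
                 module_names = as.character(module_names),
                 k = length(assignment)),
            class = "module_map")
}

#' @export
print.module_map <- function(x, ...) {
  cat("Module map:", x$k, "landmarks in", length(x$module_names), "modules\n")
  print(table(factor(x$assignment, levels = x$module_names)))
  invisible(x)
}

#' Landmark index sets per module
#' @param map a `module_map`
#' @return named list of integer vectors
#' @export
module_indices <- function(map) {
  lapply(stats::setNames(map$module_names, map$module_names),
         function(m) which(map$assignment == m))
}

#' Read/write a module map as a two-column CSV (landmark, module)
#' @param path CSV file with integer column `landmark` and column `module`
#' @return a `module_map`
#' @export
read_module_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("landmark", "module") %in% names(df))) {
    stop("module map CSV needs 'landmark' and 'module' columns")
  }
  df <- df[order(df$landmark), ]
  if (!identical(as.integer(df$landmark), seq_len(nrow(df)))) {
    stop("landmark indices must be 1..k with no gaps")
  }
  module_map(df$module)
}

#' @rdname read_module_map
#' @param map a `module_map` to write
#' @export
write_module_map <- function(map, path) {
  utils::write.csv(data.frame(landmark = seq_len(map$k),
                              module = map$assignment),
                   path, row.names = FALSE)
  invisible(path)
}

#' Reconcile taxa between species-level shape data and a phylogeny
#'
#' Labels are normalized for matching only (whitespace trimmed, internal spaces
#' replaced by underscores, case-sensitive); originals are preserved in the
#' output. Both inputs are pruned to the intersection and returned in the same
#' (sorted) species order. Idempotent.
#'
#' @param shapes species-level shapes: a `k x d x n` array whose third dimnames
#'   are species, or an object with a `$coords` array so named
#' @param tree an [ape::phylo]
#' @return list with `shapes` (array), `tree`, and `report` listing taxa
#'   dropped from each side
#' @export
match_taxa <- function(shapes, tree) {
  arr <- if (is.list(shapes) && !is.null(shapes$coords)) shapes$coords else shapes
  sp <- dimnames(arr)[[3L]]
  if (is.null(sp)) stop("shape array must carry species names in dimnames")
  key_s <- normalize_taxon(sp)
  key_t <- normalize_taxon(tree$tip.label)
  common <- intersect(key_s, key_t)
  if (length(common) == 0L) stop("no species shared between shapes and tree")
  drop_s <- sp[!key_s %in% common]
  drop_t <- tree$tip.label[!key_t %in% common]
  tree2 <- if (length(drop_t)) ape::drop.tip(tree, drop_t) else tree
  # shapes follow the pruned tree's tip order so rows of downstream matrices
  # line up with the tree covariance without further bookkeeping
  ord <- match(normalize_taxon(tree2$tip.label), key_s)
  arr2 <- arr[, , ord, drop = FALSE]
  dimnames(arr2)[[3L]] <- sp[ord]
  list(shapes = arr2, tree = tree2,
       report = list(dropped_from_shapes = drop_s, dropped_from_tree = drop_t,
                     n_common = length(common)))
}
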