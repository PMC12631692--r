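#' Build a molecular graph with SMILES-positional node order
#'
#' Converts a parsed molecule and its feature matrix into an undirected
#' heavy-atom graph. Node `i` is the `i`-th atom token of the raw SMILES
#' string; this positional identity is what the single-node readouts
#' exploit (the first SMILES atom is the most weakly connected, the last is
#' an outer atom). Bond order and aromaticity never enter the graph: edges
#' are plain unordered pairs.
#'
#' @param mol A `molgat_mol`.
#' @param features Numeric matrix with one row per heavy atom (usually the
#'   N x 35 matrix from [node_feature_matrix()]).
#' @param target Scalar regression target attached to the graph.
#' @return An object of class `molgat_graph`: list with `n_nodes`, `edges`
#'   (m x 2 integer matrix, 1-based, i < j, no duplicates), `node_features`,
#'   `smiles`, `target`.
#' @export
build_graph <- function(mol, features, target = NA_real_) {
  stopifnot(inherits(mol, "molgat_mol"), is.matrix(features))
  n <- nrow(mol$atoms)
  if (nrow(features) != n) {
    rlang::abort(paste0("feature matrix has ", nrow(features),
                        " rows but the molecule has ", n, " heavy atoms"))
  }
  e <- cbind(pmin(mol$bonds$i, mol$bonds$j),
             pmax(mol$bonds$i, mol$bonds$j))
  e <- unique(e)
  storage.mode(e) <- "integer"
  structure(
    list(n_nodes = n, edges = e, node_features = features,
         smiles = mol$smiles, target = as.numeric(target)),
    class = "molgat_graph")
}

#' @export
print.molgat_graph <- function(x, ...) {
  cat("<molgat_graph> ", x$smiles, ": ", x$n_nodes, " nodes, ",
      nrow(x$edges), " edges, ", ncol(x$node_features),
      " features/node\n", sep = "")
  invisible(x)
}

#' Terminal node positions of a graph
#'
#' Returns the 1-based indices of the first, second, penultimate and last
#' SMILES-position nodes, clamped into range for graphs with fewer than
#' four nodes (a 1-node graph returns all ones).
#'
#' @param graph A `molgat_graph` (or anything with `n_nodes`).
#' @return Named integer vector `(first, second, penultimate, last)`.
#' @export
terminal_positions <- function(graph) {
  n <- if (is.numeric(graph)) as.integer(graph) else graph$n_nodes
  stopifnot(n >= 1L)
  c(first = 1L, second = min(2L, n), penultimate = max(n - 1L, 1L),
    last = n)
}

#' Featurize a dataset into molecular graphs
#'
#' The main featurization pipeline: parses every SMILES (one batched RDKit
#' call), builds the seeded 3D conformer, assembles each N x 35 feature
#' matrix and returns graphs ready for the network. Rows whose SMILES fails
#' to parse and rows whose conformer embedding or charge assignment fails
#' are dropped with a warning, mirroring the pragmatic removal of
#' geometry-failing molecules from benchmark sets; the dropped rows are
#' reported in the `dropped` attribute.
#'
#' @param data A data frame with columns `smiles` and `target` (e.g. from
#'   [load_dataset()] or [generate_dataset()]).
#' @param seed Integer seed for conformer embedding.
#' @return A tibble with columns `smiles`, `target` and a list-column
#'   `graph` of `molgat_graph` objects, one row per surviving molecule, in
#'   input order. Attribute `dropped` is a tibble (`row`, `smiles`,
#'   `reason`).
#' @export
featurize_graphs <- function(data, seed = 1L) {
  stopifnot(is.data.frame(data), all(c("smiles", "target") %in% names(data)))
  res <- mols_from_smiles(data$smiles, gen3d = TRUE, seed = seed)
  n <- nrow(data)
  graphs <- vector("list", n)
  reasons <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    mol <- res$mols[[i]]
    if (is.null(mol)) {
      reasons[i] <- "parse_failure"
      next
    }
    feat <- tryCatch(node_feature_matrix(mol), error = function(e) e)
    if (inherits(feat, "error")) {
      reasons[i] <- "geometry_failure"
      next
    }
    graphs[[i]] <- build_graph(mol, feat, target = data$target[[i]])
  }
  keep <- is.na(reasons)
  dropped <- tibble::tibble(row = which(!keep),
                            smiles = data$smiles[!keep],
                            reason = reasons[!keep])
  if (nrow(dropped) > 0L) {
    rlang::warn(paste0(nrow(dropped), " molecule(s) dropped during ",
                       "featurization (",
                       paste(unique(dropped$reason), collapse = ", "), ")"))
  }
  out <- tibble::tibble(smiles = data$smiles[keep],
                        target = as.numeric(data$target[keep]),
                        graph = graphs[keep])
  attr(out, "dropped") <- dropped
  out
}

# Collate a list of graphs into one disjoint-union batch for the network:
# stacked feature matrix, directed edge lists (both bond directions plus
# one self-loop per node), per-graph node offsets and sizes.
as_graph_batch <- function(graphs) {
  stopifnot(length(graphs) >= 1L)
  sizes <- vapply(graphs, function(g) as.integer(g$n_nodes), integer(1))
  offsets <- c(0L, cumsum(sizes)[-length(sizes)])
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  el <- purrr::map2(graphs, offsets, function(g, off) {
    if (nrow(g$edges) == 0L) return(NULL)
    rbind(g$edges + off, g$edges[, 2:1, drop = FALSE] + off)
  })
  e <- do.call(rbind, el)
  nt <- sum(sizes)
  src <- c(if (!is.null(e)) e[, 1L], seq_len(nt))
  dst <- c(if (!is.null(e)) e[, 2L], seq_len(nt))
  list(X = X, src = as.integer(src), dst = as.integer(dst),
       n_nodes = nt, sizes = sizes, offsets = offsets,
       targets = vapply(graphs, function(g) g$target, numeric(1)))
}
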