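# Shared fixtures and independent oracles for the test suite.

# Independent SMILES atom-token scanner: a character-walking state machine,
# deliberately implemented differently from the package's regex scanner so
# the two can cross-check each other. Returns the element symbols of the
# atom tokens in order.
scan_elements_oracle <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  organic2 <- c("Cl", "Br")
  organic1 <- c("B", "C", "N", "O", "P", "S", "F", "I",
                "b", "c", "n", "o", "p", "s")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (chars[j] != "]") j <- j + 1L
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      inner <- sub("^[0-9]+", "", inner)          # isotope
      m <- regmatches(inner,
                      regexpr("^([A-Z][a-z]?|se|as|[bcnops])", inner))
      el <- m
      substr(el, 1, 1) <- toupper(substr(el, 1, 1))
      out <- c(out, el)
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% organic2) {
      out <- c(out, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch %in% organic1) {
      el <- ch
      substr(el, 1, 1) <- toupper(substr(el, 1, 1))
      out <- c(out, el)
      i <- i + 1L
    } else {
      i <- i + 1L                                  # bonds, rings, branches
    }
  }
  out
}

# 50 hand-picked single-fragment SMILES spanning chains, branches, rings,
# aromatics, charges, two-letter elements and bracket atoms.
fixture_smiles <- c(
  "C", "O", "CC", "CO", "CCO", "CCC", "COC", "CCCO", "CC(C)C", "CC(C)O",
  "C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "C1CCOC1", "c1ccccc1",
  "c1ccccc1O", "c1ccccc1C", "c1ccccc1N", "Cc1ccccc1C", "c1ccncc1",
  "c1cc[nH]c1", "CC(=O)O", "CC(=O)N", "CC(=O)OC", "CC#N", "C=C", "C#C",
  "CC=O", "OC=O", "CCCl", "CCBr", "CCI", "CCF", "ClCCCl", "FC(F)F",
  "CS", "CSC", "CCS", "CN(C)C", "C[N+](C)(C)C", "CC(=O)[O-]",
  "C[C@H](N)C(=O)O", "OCC(O)CO", "CCOCC", "CC(C)(C)C", "CCCCCCCC",
  "c1ccc2ccccc2c1", "OCc1ccccc1", "N#Cc1ccccc1")

# Featurized fixtures are expensive (one RDKit call + conformers), so they
# are built once per test session on demand.
.fixture_env <- new.env(parent = emptyenv())

fixture_graphs <- function() {
  if (is.null(.fixture_env$graphs)) {
    data <- tibble::tibble(smiles = fixture_smiles,
                           target = seq_along(fixture_smiles) / 10)
    .fixture_env$graphs <- suppressWarnings(featurize_graphs(data, seed = 7))
  }
  .fixture_env$graphs
}

fixture_mols <- function() {
  if (is.null(.fixture_env$mols)) {
    .fixture_env$mols <- mols_from_smiles(fixture_smiles, gen3d = FALSE)$mols
  }
  .fixture_env$mols
}

# Random disjoint chain-plus-chord graphs with arbitrary features, for
# model-level properties that do not need chemistry.
random_graph <- function(n, p = 7L) {
  edges <- if (n >= 2L) cbind(seq_len(n - 1L), 2:n)
           else matrix(integer(0), 0L, 2L)
  if (n >= 4L) edges <- rbind(edges, c(1L, n))    # one chord/cycle
  storage.mode(edges) <- "integer"
  structure(list(n_nodes = as.integer(n), edges = edges,
                 node_features = matrix(stats::rnorm(n * p), n, p),
                 smiles = "synthetic", target = stats::rnorm(1)),
            class = "molgat_graph")
}

# Apply a node permutation to a graph (relabel edges, permute features).
permute_graph <- function(g, perm) {
  inv <- order(perm)
  e <- cbind(inv[g$edges[, 1L]], inv[g$edges[, 2L]])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  storage.mode(e) <- "integer"
  structure(list(n_nodes = g$n_nodes, edges = e,
                 node_features = g$node_features[perm, , drop = FALSE],
                 smiles = g$smiles, target = g$target),
            class = "molgat_graph")
}

# Small synthetic featurized dataset cache keyed by mode, for training
# tests.
fixture_synth <- function(mode, n = 60L, seed = 3L, noise_sd = 0.1) {
  key <- paste(mode, n, seed)
  if (is.null(.fixture_env[[key]])) {
    spec <- synthetic_spec(n_molecules = n, grammar = "mixed",
                           target_mode = mode, noise_sd = noise_sd,
                           seed = seed)
    .fixture_env[[key]] <- attr(generate_dataset(spec), "features")
  }
  .fixture_env[[key]]
}
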