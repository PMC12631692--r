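test_that("grammar templates expand as specified", {
  spec <- synthetic_spec(n_molecules = 5, grammar = "alkane_chain",
                         size_range = c(8, 8), seed = 1)
  expect_equal(unique(generate_molecules(spec)), "CCCCCCCC")
  spec <- synthetic_spec(n_molecules = 3, grammar = "alcohol",
                         size_range = c(3, 3), seed = 1)
  smi <- generate_molecules(spec)
  expect_equal(unique(smi), "CCO")
  tok <- smiles_atom_tokens(smi[1])
  expect_equal(tok$element[nrow(tok)], "O")  # hydroxyl oxygen is last
})

test_that("every emitted SMILES parses, for every grammar", {
  for (grammar in c("alkane_chain", "alcohol", "ether", "mixed",
                    "aromatic_mixed")) {
    spec <- synthetic_spec(n_molecules = 25, grammar = grammar, seed = 2)
    smi <- generate_molecules(spec)
    expect_length(smi, 25L)
    res <- mols_from_smiles(smi, gen3d = FALSE)
    expect_length(res$failed, 0L)
    sizes <- vapply(res$mols, function(m) nrow(m$atoms), integer(1))
    expect_true(all(sizes >= 2L & sizes <= 12L))
  }
})

test_that("generation is deterministic: same spec, same bytes", {
  spec <- synthetic_spec(n_molecules = 30, grammar = "aromatic_mixed",
                         target_mode = "terminal_atom", seed = 5)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_dataset(d1, f1)
  write_dataset(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("constant mode assigns exactly 1 to every molecule", {
  ds <- generate_dataset(synthetic_spec(n_molecules = 12,
                                        target_mode = "constant",
                                        seed = 3))
  expect_identical(ds$target, rep(1, nrow(ds)))
})

test_that("noise-free global_linear targets reproduce w . g", {
  spec <- synthetic_spec(n_molecules = 25, grammar = "mixed",
                         target_mode = "global_linear", noise_sd = 0,
                         seed = 4)
  ds <- generate_dataset(spec)
  feats <- attr(ds, "features")
  gnames <- c(feature_names("molecular"), feature_names("geometry"))
  G <- do.call(rbind,
               lapply(feats$graph, function(g) g$node_features[1, gnames]))
  Gz <- apply(G, 2, function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  expect_equal(ds$target,
               drop(Gz %*% unname(spec$effect_weights[gnames])),
               tolerance = 1e-9)
})

test_that("global_linear data is linearly explainable from the 21
           global columns", {
  spec <- synthetic_spec(n_molecules = 80, grammar = "aromatic_mixed",
                         target_mode = "global_linear", noise_sd = 0.1,
                         seed = 6)
  ds <- generate_dataset(spec)
  feats <- attr(ds, "features")
  gnames <- c(feature_names("molecular"), feature_names("geometry"))
  G <- do.call(rbind,
               lapply(feats$graph, function(g) g$node_features[1, gnames]))
  df <- as.data.frame(G)
  df$y <- ds$target
  ols <- lm(y ~ ., data = df)
  expect_lte(sd(residuals(ols)), 1.1 * 0.1)
})

test_that("terminal_atom targets encode the last SMILES atom", {
  spec <- synthetic_spec(n_molecules = 2, target_mode = "terminal_atom",
                         noise_sd = 0, seed = 7)
  ds <- assign_targets(c("CCO", "CCC"), spec)
  expect_identical(ds$target, c(2, -2))
})

test_that("featurized attribute carries graphs with assigned targets", {
  ds <- generate_dataset(synthetic_spec(n_molecules = 10, seed = 8))
  feats <- attr(ds, "features")
  expect_equal(nrow(feats), nrow(ds))
  expect_identical(feats$target, ds$target)
  tg <- vapply(feats$graph, function(g) g$target, numeric(1))
  expect_identical(tg, ds$target)
  expect_equal(ncol(feats$graph[[1]]$node_features), 35L)
})
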