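test_that("split sizes follow largest-remainder rounding", {
  d100 <- tibble::tibble(x = 1:100)
  parts <- split_dataset(d100, c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(vapply(parts, nrow, integer(1)),
               c(train = 80L, val = 10L, test = 10L))
  d101 <- tibble::tibble(x = 1:101)
  parts <- split_dataset(d101, c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(sum(vapply(parts, nrow, integer(1))), 101L)
  expect_equal(sort(unname(unlist(lapply(parts, function(p) p$x)))), 1:101)
  expect_identical(split_dataset(d101, seed = 9),
                   split_dataset(d101, seed = 9))
  expect_error(split_dataset(d100, c(0.8, 0.1, 0.2)), "summing to 1")
  expect_error(split_dataset(tibble::tibble(x = 1:5)), "at least 10")
})

test_that("rmse matches a brute-force two-pass oracle", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), 3.5355339, tolerance = 1e-6)
  set.seed(8)
  p <- rnorm(50)
  t <- rnorm(50)
  oracle <- {
    acc <- 0
    for (i in seq_along(p)) acc <- acc + (p[i] - t[i])^2
    sqrt(acc / length(p))
  }
  expect_equal(rmse(p, t), oracle, tolerance = 1e-10)
  expect_equal(rmse(3 * p, 3 * t), 3 * rmse(p, t), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("the network fits a constant target", {
  feats <- fixture_synth("constant", n = 40L, seed = 3L)
  parts <- split_dataset(feats, c(0.8, 0.1, 0.1), seed = 2)
  fit <- train_model(parts$train, parts$val, model_config(seed = 1),
                     train_config(epochs = 300L,
                                  early_stop_patience = 300L, seed = 2))
  expect_lt(fit$best_val_rmse, 0.05)
})

test_that("training is bit-for-bit reproducible from its seeds", {
  feats <- fixture_synth("terminal_atom", n = 30L, seed = 4L)
  parts <- split_dataset(feats, c(0.8, 0.1, 0.1), seed = 3)
  tc <- train_config(epochs = 25L, seed = 3)
  f1 <- train_model(parts$train, parts$val, model_config(seed = 2), tc)
  f2 <- train_model(parts$train, parts$val, model_config(seed = 2), tc)
  expect_identical(f1$model$layers, f2$model$layers)
  expect_identical(f1$history, f2$history)
})

test_that("signal in the global descriptors is recovered", {
  # global_linear generator at its stated conditions: n = 400, noise 0.1
  feats <- fixture_synth("global_linear", n = 400L, seed = 11L)
  parts <- split_dataset(feats, c(0.8, 0.1, 0.1), seed = 5)
  fit <- train_model(parts$train, parts$val, model_config(seed = 2),
                     train_config(epochs = 1500L,
                                  early_stop_patience = 300L, seed = 5))
  expect_lt(fit$best_val_rmse, 3 * 0.1)  # within 3x the noise SD
})

test_that("k-fold cross-validation partitions and reports correctly", {
  feats <- fixture_synth("constant", n = 50L, seed = 6L)
  cv <- kfold_cv(feats, model_config(seed = 1),
                 train_config(epochs = 120L, early_stop_patience = 120L,
                              k_folds = 5L, seed = 4))
  expect_equal(nrow(cv$folds), 5L)
  expect_equal(sum(cv$folds$n_test), nrow(feats))
  expect_equal(unique(cv$folds$n_test), 10L)
  expect_equal(sort(unique(cv$assignment)), 1:5)
  expect_lt(cv$fold_mean, 0.1)
  expect_error(kfold_cv(feats, tc = train_config(k_folds = 1L)),
               "at least 2")
})

test_that("node position report covers all strategies once", {
  feats <- fixture_synth("terminal_atom", n = 40L, seed = 5L)
  model <- build_model(model_config(seed = 3))
  rep <- node_position_report(model, feats, random_seed = 2)
  expect_equal(rep$strategy, readout_kinds())
  expect_equal(nrow(rep), 10L)
  expect_true(all(rep$rmse >= 0, na.rm = TRUE))
  small <- vapply(feats$graph, function(g) g$n_nodes < 5L, logical(1))
  expect_equal(attr(rep, "n_excluded_small"), sum(small))
  expect_equal(rep$n[rep$strategy == "middle_mean"], sum(!small))
  expect_error(node_position_report(model, feats[0, ]), "empty")
})

test_that("a constant-output model scores identically at all positions", {
  feats <- fixture_synth("terminal_atom", n = 30L, seed = 7L)
  model <- build_model(model_config(seed = 3))
  # zero all weights: every node prediction collapses to the final bias
  model$layers <- lapply(model$layers, function(l) {
    for (nm in setdiff(names(l), "type")) l[[nm]][] <- 0
    l
  })
  rep <- node_position_report(model, feats, random_seed = 2)
  # middle_mean scores a different (>= 5 atom) subset, so compare the rest
  same <- rep$rmse[rep$strategy != "middle_mean"]
  expect_equal(length(unique(round(same, 12))), 1L)
})

test_that("ablation harness is deterministic and honors masks", {
  feats <- fixture_synth("global_linear", n = 40L, seed = 8L)
  tc <- train_config(epochs = 40L, seed = 2)
  tab <- ablation_run(feats, list(
    full = list(),
    full_again = list(columns = 1:35),
    atoms_only = list(columns = feature_names("atomic")),
    gcn = list(layer_type = "gcn")),
    model_config(seed = 1), tc)
  expect_equal(tab$n_features, c(35L, 35L, 14L, 35L))
  expect_equal(tab$rmse_test[1], tab$rmse_test[2], tolerance = 1e-12)
  expect_equal(tab$layer_type, c("gat", "gat", "gat", "gcn"))
  expect_error(ablation_run(feats, list(bad = list(columns = integer(0))),
                            model_config(), tc),
               "empty feature mask")
})

test_that("canonical ablation masks have the right widths", {
  masks <- ablation_masks()
  expect_equal(unname(lengths(masks)), c(35L, 14L, 29L, 32L, 32L, 34L))
  expect_true(all(unlist(masks) %in% feature_names()))
})

test_that("random-forest descriptor baseline is seeded and sane", {
  feats <- fixture_synth("constant", n = 40L, seed = 9L)
  suppressWarnings({  # constant response triggers a regression warning
    r1 <- rf_baseline(feats, n_trees = 100L, tc = train_config(seed = 5))
    r2 <- rf_baseline(feats, n_trees = 100L, tc = train_config(seed = 5))
  })
  expect_lt(r1$rmse_test, 0.05)
  expect_identical(r1$rmse_test, r2$rmse_test)
  lin <- fixture_synth("global_linear", n = 60L, seed = 10L)
  rl <- rf_baseline(lin, n_trees = 150L, tc = train_config(seed = 5))
  expect_lt(rl$rmse_test, 5 * sd(lin$target))
})

test_that("tidy, glance and autoplot expose the fit", {
  feats <- fixture_synth("constant", n = 30L, seed = 12L)
  parts <- split_dataset(feats, c(0.8, 0.1, 0.1), seed = 2)
  fit <- train_model(parts$train, parts$val, model_config(seed = 1),
                     train_config(epochs = 15L, seed = 2))
  td <- tidy(fit)
  expect_equal(names(td), c("epoch", "train_rmse", "val_rmse"))
  expect_equal(nrow(td), 15L)
  gl <- glance(fit)
  expect_equal(gl$n_parameters, 3699L)
  expect_equal(gl$readout, "last_node")
  expect_s3_class(autoplot(fit), "ggplot")
  rep <- node_position_report(fit, parts$test)
  expect_s3_class(autoplot(rep), "ggplot")
  pred <- predict(fit, parts$test)
  expect_s3_class(plot_predictions(pred), "ggplot")
  expect_equal(nrow(pred), nrow(parts$test))
})
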