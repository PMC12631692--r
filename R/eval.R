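#' Node-position and pooling report
#'
#' Evaluates test RMSE for every readout strategy on one trained model,
#' reusing a single forward pass per molecule. This is the core diagnostic
#' of the positional-readout idea: if a property is carried by a localized
#' substructure at the end of the SMILES string, the last-node readout
#' beats the early-node readouts; if it is global, pooling wins. The
#' `middle_mean` row excludes molecules with fewer than 5 heavy atoms
#' (no middle exists) and reports how many were excluded.
#'
#' @param fit A `molgat_fit` (or `molgat_model`).
#' @param test_data Featurized tibble from [featurize_graphs()].
#' @param random_seed Seed for the random-node strategies.
#' @return A `molgat_report` tibble with columns `strategy`, `rmse`, `n`
#'   (molecules evaluated); attribute `n_excluded_small` gives the
#'   `middle_mean` exclusion count.
#' @export
node_position_report <- function(fit, test_data, random_seed = 1L) {
  model <- if (inherits(fit, "molgat_fit")) fit$model else fit
  stopifnot(inherits(model, "molgat_model"))
  if (nrow(test_data) < 1L) rlang::abort("empty test set")
  batch <- as_graph_batch(test_data$graph)
  node_pred <- forward_batch(model, batch)$pred
  targets <- batch$targets
  big <- batch$sizes >= 5L
  rows <- lapply(readout_kinds(), function(kind) {
    strategy <- readout_strategy(kind, seed = random_seed)
    if (kind == "middle_mean") {
      if (!any(big)) {
        return(tibble::tibble(strategy = kind, rmse = NA_real_, n = 0L))
      }
      sub <- as_graph_batch(test_data$graph[big])
      plan <- .readout_plan(sub, strategy)
      p <- .readout_apply(plan, forward_batch(model, sub)$pred, sub)$pred
      tibble::tibble(strategy = kind, rmse = rmse(p, targets[big]),
                     n = sum(big))
    } else {
      plan <- .readout_plan(batch, strategy)
      p <- .readout_apply(plan, node_pred, batch)$pred
      tibble::tibble(strategy = kind, rmse = rmse(p, targets),
                     n = length(targets))
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_excluded_small") <- sum(!big)
  class(out) <- c("molgat_report", class(out))
  out
}

#' k-fold cross-validation
#'
#' Splits the data into `k` seeded disjoint folds; each fold is the test
#' set once while the remainder is split 9:1 into train and validation for
#' early stopping. Reports the per-fold test RMSE under the model's
#' training readout, with mean and standard deviation.
#'
#' @param data Featurized tibble from [featurize_graphs()].
#' @param config A [model_config()].
#' @param tc A [train_config()]; `tc$k_folds` sets `k`, `tc$seed` the fold
#'   assignment.
#' @return A list with `folds` (tibble: `fold`, `n_test`, `rmse`),
#'   `fold_mean`, `fold_sd`, and `assignment` (fold id per row of `data`).
#' @export
kfold_cv <- function(data, config = model_config(), tc = train_config()) {
  k <- tc$k_folds
  n <- nrow(data)
  if (k < 2L) rlang::abort("k_folds must be at least 2")
  if (n < k) rlang::abort("need at least k records for k folds")
  assignment <- withr_seed(tc$seed, sample(rep_len(seq_len(k), n)))
  scores <- vapply(seq_len(k), function(f) {
    test <- data[assignment == f, ]
    rest <- data[assignment != f, ]
    inner <- withr_seed(tc$seed + f, sample.int(nrow(rest)))
    n_val <- max(1L, floor(nrow(rest) / 10))
    val <- rest[inner[seq_len(n_val)], ]
    tr <- rest[inner[-seq_len(n_val)], ]
    fit <- train_model(tr, val, config, tc)
    pred <- predict(fit, test)
    rmse(pred$pred, pred$target)
  }, numeric(1))
  folds <- tibble::tibble(fold = seq_len(k),
                          n_test = tabulate(assignment, k),
                          rmse = scores)
  list(folds = folds, fold_mean = mean(scores), fold_sd = stats::sd(scores),
       assignment = assignment)
}

#' Restrict graphs to a subset of feature columns
#'
#' @param data Featurized tibble.
#' @param columns Character feature names or integer column indices to keep.
#' @return The tibble with every graph's feature matrix reduced.
#' @export
subset_features <- function(data, columns) {
  if (length(columns) == 0L) rlang::abort("empty feature mask")
  data$graph <- lapply(data$graph, function(g) {
    g$node_features <- g$node_features[, columns, drop = FALSE]
    g
  })
  data
}

#' Canonical feature masks for ablations
#'
#' Named column sets covering the standard ablations: the full 35 columns;
#' atomic features only (the no-global-features variant); everything but
#' the 6 conformer descriptors; and the geometry subsets (extents only;
#' volume/dipole/angle; extents plus volume and angle).
#'
#' @return Named list of character vectors of feature names.
#' @export
ablation_masks <- function() {
  atomic <- feature_names("atomic")
  chem <- feature_names("molecular")
  list(
    full = feature_names(),
    no_global_features = atomic,
    no_geometry = c(atomic, chem),
    geometry_extents = c(atomic, chem, "width", "length", "height"),
    geometry_vol_dipole_angle = c(atomic, chem, "volume", "dipole_moment",
                                  "orientation_angle"),
    geometry_extents_vol_angle = c(atomic, chem, "volume", "width",
                                   "length", "height",
                                   "orientation_angle"))
}

#' Feature-subset and layer-type ablation harness
#'
#' Trains one model per variant under identical seeds and splits and
#' tabulates test RMSE. A variant names a feature mask (columns kept;
#' masked columns are removed, shrinking the input width) and optionally a
#' layer type or readout override. Canonical masks: all 35 columns;
#' atomic-only (drops the 21 broadcast global features); geometry subsets.
#'
#' @param data Featurized tibble (full 35-column graphs).
#' @param variants Named list; each element a list with optional fields
#'   `columns` (feature names/indices to keep, default all),
#'   `layer_type`, `readout`.
#' @param config Base [model_config()].
#' @param tc A [train_config()]; its `split` and `seed` fix the shared
#'   train/val/test partition.
#' @return Tibble: `variant`, `n_features`, `layer_type`, `readout`,
#'   `rmse_test`.
#' @export
ablation_run <- function(data, variants, config = model_config(),
                         tc = train_config()) {
  stopifnot(length(variants) >= 1L, !is.null(names(variants)))
  parts <- split_dataset(data, tc$split, tc$seed)
  rows <- purrr::imap(variants, function(v, nm) {
    cols <- v$columns %||% seq_len(ncol(data$graph[[1]]$node_features))
    if (length(cols) == 0L) rlang::abort("empty feature mask")
    tr <- subset_features(parts$train, cols)
    va <- subset_features(parts$val, cols)
    te <- subset_features(parts$test, cols)
    nf <- ncol(tr$graph[[1]]$node_features)
    cfg <- model_config(
      layer_type = v$layer_type %||% config$layer_type,
      n_layers = config$n_layers, hidden = config$hidden,
      n_features = nf,
      readout = v$readout %||% config$readout,
      seed = config$seed)
    fit <- train_model(tr, va, cfg, tc)
    pred <- predict(fit, te)
    tibble::tibble(variant = nm, n_features = nf,
                   layer_type = cfg$layer_type,
                   readout = cfg$readout$kind,
                   rmse_test = rmse(pred$pred, pred$target))
  })
  dplyr::bind_rows(rows)
}

#' Random-forest baseline on expert-crafted descriptors
#'
#' Fits a random forest on the molecule-level descriptor table (the 21
#' global features each molecule broadcasts to its nodes) under the same
#' seeded train/validation/test split as the network, and reports test
#' RMSE. A strong descriptor-only baseline shows how much of the signal
#' the expert features already carry without any message passing.
#'
#' @param data Featurized tibble.
#' @param n_trees Number of trees.
#' @param tc A [train_config()] fixing split fractions and seed.
#' @return A list with `rmse_test`, `n_train`, `n_test`, and the fitted
#'   `forest`.
#' @export
rf_baseline <- function(data, n_trees = 500L, tc = train_config()) {
  desc <- .descriptor_table(data)
  parts <- split_dataset(desc, tc$split, tc$seed)
  xcols <- setdiff(names(desc), "target")
  fit <- withr_seed(tc$seed, randomForest::randomForest(
    x = as.data.frame(parts$train[, xcols]),
    y = parts$train$target, ntree = n_trees))
  pred <- stats::predict(fit, as.data.frame(parts$test[, xcols]))
  list(rmse_test = rmse(as.numeric(pred), parts$test$target),
       n_train = nrow(parts$train), n_test = nrow(parts$test),
       forest = fit)
}

# One row per molecule: the 21 broadcast global descriptors + target.
.descriptor_table <- function(data) {
  glob <- feature_names("molecular")
  geom <- feature_names("geometry")
  rows <- lapply(data$graph, function(g) {
    g$node_features[1L, c(glob, geom), drop = FALSE]
  })
  out <- tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
  out$target <- data$target
  out
}
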