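#' Training configuration
#'
#' Training minimizes mean squared error between the readout of the
#' per-node predictions and the target, with RMSprop. The loss is the
#' smooth counterpart of the reported metric (RMSE). Full-batch updates
#' are the default: at ~3.7K parameters the whole training set fits in one
#' gradient step.
#'
#' @param learning_rate RMSprop step size.
#' @param epochs Maximum number of epochs.
#' @param batch_size Graphs per update; `NULL` means full batch.
#' @param split Train/validation/test fractions, summing to 1.
#' @param k_folds Folds for [kfold_cv()].
#' @param seed Seed controlling splits, shuffling and any random readout.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping; the returned model is the best-validation checkpoint.
#' @param init_scale Rescale each hidden layer's weights once, before
#'   training, so its pre-activation standard deviation on the training
#'   batch is about 1. The node features are deliberately left on their
#'   natural scales (only three atomic features carry fixed scalings), so
#'   without this the first tanh starts deeply saturated and early
#'   training is spent escaping it. The rescale is deterministic.
#' @return A `molgat_train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 2000L,
                         batch_size = NULL, split = c(0.8, 0.1, 0.1),
                         k_folds = 5L, seed = 1L,
                         early_stop_patience = 100L, init_scale = TRUE) {
  if (length(split) != 3L || any(split <= 0) ||
      abs(sum(split) - 1) > 1e-9) {
    rlang::abort("split must be three positive fractions summing to 1")
  }
  structure(list(optimizer = "rmsprop",
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = if (!is.null(batch_size))
                   as.integer(batch_size),
                 split = split, k_folds = as.integer(k_folds),
                 seed = as.integer(seed),
                 early_stop_patience = as.integer(early_stop_patience),
                 init_scale = isTRUE(init_scale)),
            class = "molgat_train_config")
}

#' Root mean squared error
#'
#' @param predictions,targets Equal-length numeric vectors.
#' @return `sqrt(mean((predictions - targets)^2))`.
#' @export
rmse <- function(predictions, targets) {
  if (length(predictions) != length(targets) || length(targets) < 1L) {
    rlang::abort("predictions and targets must have equal length >= 1")
  }
  sqrt(mean((predictions - targets)^2))
}

#' Random train/validation/test split
#'
#' Sizes follow largest-remainder rounding of the fractions, so they are
#' disjoint, cover the data, and are deterministic in the seed.
#'
#' @param data A data frame (one row per molecule).
#' @param fractions Three positive fractions summing to 1.
#' @param seed Integer seed.
#' @return Named list of tibbles `train`, `val`, `test`.
#' @export
split_dataset <- function(data, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(is.data.frame(data))
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    rlang::abort("fractions must be three positive values summing to 1")
  }
  n <- nrow(data)
  if (n < 10L) rlang::abort("need at least 10 records to split")
  exact <- fractions * n
  sizes <- floor(exact)
  rem <- n - sum(sizes)
  if (rem > 0L) {
    extra <- order(exact - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  perm <- withr_seed(seed, sample.int(n))
  idx <- split(perm, rep(c("train", "val", "test"), times = sizes))
  lapply(idx[c("train", "val", "test")],
         function(i) tibble::as_tibble(data[sort(i), , drop = FALSE]))
}

# Readout bookkeeping over a collated batch: for the linear strategies a
# sparse (index, weight, graph) triplet list; max/min pool resolve their
# node per forward pass.
.readout_plan <- function(batch, strategy) {
  sizes <- batch$sizes
  offs <- batch$offsets
  m <- length(sizes)
  kind <- strategy$kind
  if (kind %in% c("max_pool", "min_pool")) {
    return(list(type = kind, m = m))
  }
  pick <- switch(kind,
    first_node = lapply(seq_len(m), function(g) offs[g] + 1L),
    second_node = lapply(seq_len(m), function(g) offs[g] + min(2L, sizes[g])),
    penultimate_node = lapply(seq_len(m),
                              function(g) offs[g] + max(sizes[g] - 1L, 1L)),
    last_node = lapply(seq_len(m), function(g) offs[g] + sizes[g]),
    middle_mean = lapply(seq_len(m), function(g) {
      if (sizes[g] < 5L) {
        rlang::abort("middle_mean needs at least 5 nodes in every graph",
                     class = "molgat_middle_mean_error")
      }
      offs[g] + 3:(sizes[g] - 2L)
    }),
    mean_pool = lapply(seq_len(m), function(g) offs[g] + seq_len(sizes[g])),
    random_node = withr_seed(strategy$seed, lapply(seq_len(m), function(g) {
      offs[g] + sample.int(sizes[g], 1L)
    })),
    random_mean_5 = withr_seed(strategy$seed,
                               lapply(seq_len(m), function(g) {
      offs[g] + sample.int(sizes[g], 5L, replace = TRUE)
    })),
    rlang::abort(paste0("unknown readout kind ", kind)))
  idx <- unlist(pick)
  gid <- rep(seq_len(m), lengths(pick))
  wts <- unlist(lapply(pick, function(p) rep(1 / length(p), length(p))))
  list(type = "linear", idx = idx, gid = gid, wts = wts, m = m)
}

# Molecule-level predictions from node predictions under a readout plan.
.readout_apply <- function(plan, node_pred, batch) {
  if (plan$type == "linear") {
    rs <- rowsum(plan$wts * node_pred[plan$idx], plan$gid)
    out <- numeric(plan$m)
    out[as.integer(rownames(rs))] <- rs[, 1L]
    return(list(pred = out, argidx = NULL))
  }
  f <- if (plan$type == "max_pool") which.max else which.min
  argidx <- vapply(seq_along(batch$sizes), function(g) {
    seg <- node_pred[(batch$offsets[g] + 1L):(batch$offsets[g] +
                                                batch$sizes[g])]
    batch$offsets[g] + f(seg)
  }, integer(1))
  list(pred = node_pred[argidx], argidx = argidx)
}

# Scatter molecule-level prediction gradients back onto nodes.
.readout_grad <- function(plan, dmol, node_count, argidx = NULL) {
  dnode <- numeric(node_count)
  if (plan$type == "linear") {
    contrib <- rowsum(plan$wts * dmol[plan$gid], plan$idx)
    dnode[as.integer(rownames(contrib))] <- contrib[, 1L]
  } else {
    contrib <- rowsum(dmol, argidx)
    dnode[as.integer(rownames(contrib))] <- contrib[, 1L]
  }
  dnode
}

# Variance-normalizing init rescale (in the spirit of layer-sequential
# unit-variance init): walk the hidden layers in order and divide each
# layer's weight matrices by the standard deviation of its pre-activation
# on the training batch, twice for convergence. Attention coefficients are
# softmax-normalized, so the pass leaves the attention structure intact.
.init_rescale <- function(model, batch, target_sd = 1) {
  nl <- length(model$layers)
  for (k in seq_len(nl - 1L)) {
    for (iter in 1:2) {
      fwd <- forward_batch(model, batch, keep_cache = TRUE)
      s <- stats::sd(fwd$pre[[k]])
      if (!is.finite(s) || s < 1e-12) break
      f <- s / target_sd
      for (nm in intersect(c("W", "W_l", "W_r"),
                           names(model$layers[[k]]))) {
        model$layers[[k]][[nm]] <- model$layers[[k]][[nm]] / f
      }
      if (abs(f - 1) < 0.05) break
    }
  }
  model
}

.rmsprop_init <- function(layers) {
  lapply(layers, function(l) {
    lapply(l[setdiff(names(l), "type")], function(p) {
      if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
    })
  })
}

.rmsprop_step <- function(layers, grads, state, lr, alpha = 0.99,
                          eps = 1e-8) {
  for (k in seq_along(layers)) {
    for (nm in names(grads[[k]])) {
      g <- grads[[k]][[nm]]
      v <- alpha * state[[k]][[nm]] + (1 - alpha) * g^2
      state[[k]][[nm]] <- v
      layers[[k]][[nm]] <- layers[[k]][[nm]] - lr * g / (sqrt(v) + eps)
    }
  }
  list(layers = layers, state = state)
}

#' Train the network
#'
#' Full-batch (default) RMSprop on the mean squared error between
#' `readout(forward(graph))` and the target, with early stopping on
#' validation RMSE; the returned fit carries the best-validation weights
#' and the per-epoch history. Fully reproducible from the seeds in the
#' configs.
#'
#' @param train_data,val_data Featurized tibbles from [featurize_graphs()]
#'   (columns `smiles`, `target`, `graph`).
#' @param config A [model_config()]; its `readout` is the training-time
#'   readout whose loss path is optimized.
#' @param tc A [train_config()].
#' @return A `molgat_fit`: list with `model`, `config`, `train_config`,
#'   `history` (tibble of per-epoch train/val RMSE), `best_epoch`,
#'   `best_val_rmse`.
#' @export
train_model <- function(train_data, val_data, config = model_config(),
                        tc = train_config()) {
  stopifnot(nrow(train_data) >= 1L)
  model <- build_model(config)
  batches <- .make_batches(train_data$graph, tc)
  batches <- lapply(batches, function(b) {
    b$plan <- .readout_plan(b$batch, config$readout)
    b
  })
  val_batch <- if (nrow(val_data) > 0L) as_graph_batch(val_data$graph)
  val_plan <- if (!is.null(val_batch)) .readout_plan(val_batch,
                                                     config$readout)
  if (tc$init_scale) {
    model <- .init_rescale(model, batches[[1L]]$batch)
  }
  state <- .rmsprop_init(model$layers)
  best <- list(val = Inf, layers = model$layers, epoch = 0L)
  hist_tr <- numeric(0)
  hist_val <- numeric(0)
  stall <- 0L
  for (epoch in seq_len(tc$epochs)) {
    sq_sum <- 0
    n_mol <- 0L
    for (b in batches) {
      fwd <- forward_batch(model, b$batch, keep_cache = TRUE)
      ro <- .readout_apply(b$plan, fwd$pred, b$batch)
      resid <- ro$pred - b$batch$targets
      sq_sum <- sq_sum + sum(resid^2)
      n_mol <- n_mol + length(resid)
      if (any(!is.finite(resid))) {
        rlang::abort(paste0("non-finite loss at epoch ", epoch,
                            "; try a smaller learning rate"),
                     class = "molgat_training_error")
      }
      dmol <- 2 * resid / length(resid)
      dnode <- .readout_grad(b$plan, dmol, b$batch$n_nodes, ro$argidx)
      grads <- backward_batch(model, b$batch, fwd, dnode)
      upd <- .rmsprop_step(model$layers, grads, state, tc$learning_rate)
      model$layers <- upd$layers
      state <- upd$state
    }
    hist_tr[epoch] <- sqrt(sq_sum / n_mol)
    if (!is.null(val_batch)) {
      vp <- .readout_apply(val_plan,
                           forward_batch(model, val_batch)$pred,
                           val_batch)$pred
      vr <- rmse(vp, val_batch$targets)
      hist_val[epoch] <- vr
      if (vr < best$val - 1e-12) {
        best <- list(val = vr, layers = model$layers, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tc$early_stop_patience) break
      }
    } else {
      best <- list(val = hist_tr[epoch], layers = model$layers,
                   epoch = epoch)
    }
  }
  model$layers <- best$layers
  structure(
    list(model = model, config = config, train_config = tc,
         history = tibble::tibble(
           epoch = seq_along(hist_tr), train_rmse = hist_tr,
           val_rmse = if (length(hist_val)) hist_val else NA_real_),
         best_epoch = best$epoch, best_val_rmse = best$val),
    class = "molgat_fit")
}

.make_batches <- function(graphs, tc) {
  n <- length(graphs)
  groups <- if (is.null(tc$batch_size) || tc$batch_size >= n) {
    list(seq_len(n))
  } else {
    perm <- withr_seed(tc$seed, sample.int(n))
    split(perm, ceiling(seq_along(perm) / tc$batch_size))
  }
  # batches are collated once and fixed; random readout draws are frozen
  # across epochs, keeping training deterministic
  lapply(groups, function(ix) {
    list(batch = as_graph_batch(graphs[ix]), idx = ix)
  })
}

#' Learning-rate grid search
#'
#' Trains one model per candidate learning rate and returns the fit with
#' the best validation RMSE. Off by default everywhere; the package
#' default rate was fixed from this grid once.
#'
#' @param train_data,val_data Featurized tibbles.
#' @param config A [model_config()].
#' @param tc A [train_config()]; its `learning_rate` is overridden.
#' @param grid Candidate learning rates.
#' @return The best `molgat_fit`, with the searched grid and per-rate
#'   validation RMSEs in attribute `grid_results`.
#' @export
tune_learning_rate <- function(train_data, val_data,
                               config = model_config(),
                               tc = train_config(),
                               grid = c(1e-2, 5e-3, 1e-3)) {
  stopifnot(length(grid) >= 1L)
  fits <- lapply(grid, function(lr) {
    tc$learning_rate <- lr
    train_model(train_data, val_data, config, tc)
  })
  scores <- vapply(fits, function(f) f$best_val_rmse, numeric(1))
  best <- fits[[which.min(scores)]]
  attr(best, "grid_results") <- tibble::tibble(learning_rate = grid,
                                               val_rmse = scores)
  best
}

#' Predict molecular targets
#'
#' @param object A `molgat_fit`.
#' @param newdata A featurized tibble from [featurize_graphs()].
#' @param strategy Optional readout override (defaults to the fit's
#'   training readout).
#' @param ... Unused.
#' @return `newdata` with a `pred` column appended.
#' @export
predict.molgat_fit <- function(object, newdata, strategy = NULL, ...) {
  strategy <- strategy %||% object$config$readout
  batch <- as_graph_batch(newdata$graph)
  plan <- .readout_plan(batch, strategy)
  node_pred <- forward_batch(object$model, batch)$pred
  dplyr::mutate(dplyr::select(newdata, -dplyr::any_of("pred")),
                pred = .readout_apply(plan, node_pred, batch)$pred)
}

#' @export
print.molgat_fit <- function(x, ...) {
  cat("<molgat_fit> ", x$config$layer_type, " x", x$config$n_layers,
      ", readout ", x$config$readout$kind,
      ", best val RMSE ", signif(x$best_val_rmse, 4),
      " at epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}
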