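#' Model configuration
#'
#' The network is a stack of `n_layers` graph convolutions (35 -> hidden,
#' hidden -> hidden ..., hidden -> 1) with a hyperbolic tangent after every
#' layer except the last; the raw per-node outputs of the final layer are
#' the node predictions, and a readout strategy turns them into one
#' molecular prediction. The default - five single-head graph-attention
#' layers of width 28 - has 3699 trainable parameters: deliberately tiny,
#' so the expert-crafted global features, not capacity, do the heavy
#' lifting.
#'
#' @param layer_type One of `"gat"` (additive single-head attention),
#'   `"gatv2"`, `"gcn"`.
#' @param n_layers Number of convolution layers (>= 2).
#' @param hidden Hidden width.
#' @param n_features Input feature width (35 for the full feature set;
#'   ablations that remove columns shrink it).
#' @param readout A [readout_strategy()]; used as the training-time readout.
#' @param seed Integer seed for weight initialization.
#' @return A `molgat_config` list.
#' @export
model_config <- function(layer_type = "gat", n_layers = 5L, hidden = 28L,
                         n_features = 35L,
                         readout = readout_strategy("last_node"),
                         seed = 1L) {
  if (!layer_type %in% names(.layer_registry)) {
    rlang::abort(paste0("unknown layer type '", layer_type,
                        "'; registry: ",
                        paste(names(.layer_registry), collapse = ", ")))
  }
  stopifnot(n_layers >= 2L, hidden >= 1L, n_features >= 1L)
  structure(list(layer_type = layer_type, n_layers = as.integer(n_layers),
                 hidden = as.integer(hidden),
                 n_features = as.integer(n_features),
                 activation = "tanh", attention_heads = 1L,
                 readout = readout, seed = as.integer(seed)),
            class = "molgat_config")
}

#' Readout strategies: from per-node outputs to one prediction
#'
#' Positional readouts index a single SMILES-position node (first, second,
#' penultimate, last, with degenerate clamping on tiny graphs);
#' `middle_mean` averages all nodes except the first two and last two and
#' requires at least 5 nodes; `random_node` picks one node uniformly,
#' `random_mean_5` averages 5 uniform draws with replacement; the pooling
#' kinds reduce over all nodes.
#'
#' @param kind One of `"first_node"`, `"second_node"`,
#'   `"penultimate_node"`, `"last_node"`, `"middle_mean"`,
#'   `"random_node"`, `"random_mean_5"`, `"mean_pool"`, `"max_pool"`,
#'   `"min_pool"`.
#' @param seed Seed used by the random kinds.
#' @return A `molgat_readout` list.
#' @export
readout_strategy <- function(kind = "last_node", seed = 1L) {
  kinds <- c("first_node", "second_node", "penultimate_node", "last_node",
             "middle_mean", "random_node", "random_mean_5", "mean_pool",
             "max_pool", "min_pool")
  kind <- match.arg(kind, kinds)
  structure(list(kind = kind, seed = as.integer(seed)),
            class = "molgat_readout")
}

#' All readout kinds, in report order
#' @return Character vector of the 10 strategy kinds.
#' @export
readout_kinds <- function() {
  c("first_node", "second_node", "penultimate_node", "last_node",
    "middle_mean", "random_node", "random_mean_5", "mean_pool",
    "max_pool", "min_pool")
}

#' Apply a readout strategy to a vector of node predictions
#'
#' @param node_preds Numeric vector, one prediction per node in SMILES
#'   order.
#' @param strategy A [readout_strategy()] or a kind string.
#' @return A single number.
#' @export
readout <- function(node_preds, strategy) {
  if (is.character(strategy)) strategy <- readout_strategy(strategy)
  n <- length(node_preds)
  stopifnot(n >= 1L)
  tp <- terminal_positions(n)
  switch(strategy$kind,
    first_node = node_preds[[tp[["first"]]]],
    second_node = node_preds[[tp[["second"]]]],
    penultimate_node = node_preds[[tp[["penultimate"]]]],
    last_node = node_preds[[tp[["last"]]]],
    middle_mean = {
      if (n < 5L) {
        rlang::abort("middle_mean needs at least 5 nodes",
                     class = "molgat_middle_mean_error")
      }
      mean(node_preds[3:(n - 2L)])
    },
    random_node = {
      withr_seed(strategy$seed, node_preds[[sample.int(n, 1L)]])
    },
    random_mean_5 = {
      withr_seed(strategy$seed,
                 mean(node_preds[sample.int(n, 5L, replace = TRUE)]))
    },
    mean_pool = mean(node_preds),
    max_pool = max(node_preds),
    min_pool = min(node_preds))
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Build a network from a configuration
#'
#' Layer dimensions are `n_features -> hidden`, `hidden -> hidden` repeated
#' `n_layers - 2` times, then `hidden -> 1`. Weights are Glorot-initialized
#' deterministically from `config$seed`; biases start at zero.
#'
#' @param config A [model_config()].
#' @return A `molgat_model`.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "molgat_config"))
  dims <- c(config$n_features, rep(config$hidden, config$n_layers - 1L), 1L)
  layers <- withr_seed(config$seed, {
    lapply(seq_len(config$n_layers), function(k) {
      layer_init(config$layer_type, dims[k], dims[k + 1L])
    })
  })
  structure(list(config = config, layers = layers, dims = dims),
            class = "molgat_model")
}

#' Number of trainable parameters
#'
#' @param model A `molgat_model`.
#' @return Integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "molgat_model"))
  sum(vapply(model$layers, function(l) {
    sum(vapply(l[setdiff(names(l), "type")], length, integer(1)))
  }, integer(1)))
}

# Forward pass over a collated batch. Returns per-node predictions and,
# when keep_cache, everything the backward pass needs.
forward_batch <- function(model, batch, keep_cache = FALSE) {
  X <- batch$X
  nl <- length(model$layers)
  caches <- if (keep_cache) vector("list", nl)
  pre <- if (keep_cache) vector("list", nl)
  for (k in seq_len(nl)) {
    out <- layer_forward(model$layers[[k]], X, batch, keep_cache)
    if (keep_cache) caches[[k]] <- out$cache
    H <- out$H
    if (k < nl) {
      if (keep_cache) pre[[k]] <- H
      X <- tanh(H)
    } else {
      X <- H
    }
  }
  list(pred = as.numeric(X), caches = caches, pre = pre)
}

# Backward pass: grad of loss wrt per-node predictions -> parameter grads.
backward_batch <- function(model, batch, fwd, dpred) {
  nl <- length(model$layers)
  G <- matrix(dpred, ncol = 1L)
  grads <- vector("list", nl)
  for (k in rev(seq_len(nl))) {
    bk <- layer_backward(model$layers[[k]], G, batch, fwd$caches[[k]])
    grads[[k]] <- bk$grads
    if (k > 1L) {
      G <- bk$dX * (1 - tanh(fwd$pre[[k - 1L]])^2)
    }
  }
  grads
}

#' Per-node forward pass on one graph
#'
#' @param model A `molgat_model`.
#' @param graph A `molgat_graph` whose feature width matches the model.
#' @return Numeric vector with one prediction per node, SMILES order.
#' @export
forward <- function(model, graph) {
  stopifnot(inherits(model, "molgat_model"), inherits(graph, "molgat_graph"))
  if (ncol(graph$node_features) != model$config$n_features) {
    rlang::abort(paste0("graph has ", ncol(graph$node_features),
                        " features per node but the model expects ",
                        model$config$n_features))
  }
  forward_batch(model, as_graph_batch(list(graph)))$pred
}

#' @export
print.molgat_model <- function(x, ...) {
  cat("<molgat_model> ", x$config$layer_type, " x", x$config$n_layers,
      ", dims ", paste(x$dims, collapse = "-"),
      ", ", count_parameters(x), " parameters\n", sep = "")
  invisible(x)
}
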