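# Closed-form parameter counts, derived by hand per layer type:
#   gat:   W (in*out) + a_src (out) + a_dst (out) + bias (out)
#   gatv2: W_l (in*out) + W_r (in*out) + a (out) + bias (out)
#   gcn:   W (in*out) + bias (out)
count_oracle <- function(type, dims) {
  per <- switch(type,
    gat = function(i, o) i * o + 3 * o,
    gatv2 = function(i, o) 2 * i * o + 2 * o,
    gcn = function(i, o) i * o + o)
  sum(vapply(seq_len(length(dims) - 1L),
             function(k) per(dims[k], dims[k + 1L]), numeric(1)))
}

test_that("the default network stays within the ~3.7K parameter budget", {
  model <- build_model(model_config())
  expect_equal(count_parameters(model), 3699L)
  expect_lt(abs(count_parameters(model) - 3700) / 3700, 0.03)
})

test_that("parameter counts equal the closed-form oracle per layer type", {
  for (type in c("gat", "gatv2", "gcn")) {
    for (cfg in list(list(nl = 2L, h = 1L), list(nl = 5L, h = 28L),
                     list(nl = 3L, h = 7L))) {
      model <- build_model(model_config(layer_type = type,
                                        n_layers = cfg$nl,
                                        hidden = cfg$h))
      dims <- c(35L, rep(cfg$h, cfg$nl - 1L), 1L)
      expect_equal(count_parameters(model), count_oracle(type, dims),
                   info = paste(type, cfg$nl, cfg$h))
    }
  }
})

test_that("unknown layer types name the registry", {
  expect_error(model_config(layer_type = "transformer"), "gat")
})

test_that("initialization is deterministic in the seed", {
  m1 <- build_model(model_config(seed = 42))
  m2 <- build_model(model_config(seed = 42))
  expect_identical(m1$layers, m2$layers)
  m3 <- build_model(model_config(seed = 43))
  expect_false(identical(m1$layers, m3$layers))
})

test_that("forward yields one value per node for every layer type", {
  set.seed(1)
  g1 <- random_graph(1L, 35L)
  g6 <- random_graph(6L, 35L)
  for (type in c("gat", "gatv2", "gcn")) {
    model <- build_model(model_config(layer_type = type, seed = 2))
    expect_length(forward(model, g1), 1L)
    expect_length(forward(model, g6), 6L)
  }
  expect_error(forward(build_model(model_config()), random_graph(3L, 7L)),
               "features")
})

test_that("forward is permutation-equivariant", {
  set.seed(7)
  for (type in c("gat", "gatv2", "gcn")) {
    model <- build_model(model_config(layer_type = type, n_layers = 3L,
                                      hidden = 8L, n_features = 7L,
                                      seed = 5))
    worst <- 0
    for (rep in 1:50) {
      n <- sample(3:12, 1)
      g <- random_graph(n, 7L)
      perm <- sample(n)
      gp <- permute_graph(g, perm)
      worst <- max(worst,
                   max(abs(forward(model, g)[perm] - forward(model, gp))))
    }
    expect_lt(worst, 1e-5)
  }
})

test_that("isomorphic graphs with identical features give identical
           output multisets", {
  set.seed(3)
  model <- build_model(model_config(n_layers = 3L, hidden = 8L,
                                    n_features = 7L, seed = 5))
  g <- random_graph(8L, 7L)
  gp <- permute_graph(g, sample(8))
  expect_equal(sort(forward(model, g)), sort(forward(model, gp)),
               tolerance = 1e-10)
})

test_that("hidden activations are tanh-bounded, the head is not", {
  set.seed(2)
  g <- random_graph(10L, 35L)
  model <- build_model(model_config(seed = 3))
  batch <- molgat:::as_graph_batch(list(g))
  fwd <- molgat:::forward_batch(model, batch, keep_cache = TRUE)
  for (k in seq_along(fwd$pre)) {
    if (is.null(fwd$pre[[k]])) next
    expect_true(all(abs(tanh(fwd$pre[[k]])) < 1))
  }
})

test_that("readout algebra: constants, indexing and the middle mean", {
  for (kind in readout_kinds()) {
    expect_equal(readout(rep(3.25, 7), readout_strategy(kind, seed = 1)),
                 3.25, info = kind)
  }
  expect_equal(readout(1:6, "middle_mean"), 3.5)
  expect_equal(readout(c(1, 2, 3), "last_node"), 3)
  expect_equal(readout(c(1, 2, 3), "first_node"), 1)
  expect_equal(readout(c(1, 2, 3), "second_node"), 2)
  expect_equal(readout(c(1, 2, 3), "penultimate_node"), 2)
  expect_equal(readout(c(4, 9), "mean_pool"), 6.5)
  expect_equal(readout(c(4, 9), "max_pool"), 9)
  expect_equal(readout(c(4, 9), "min_pool"), 4)
  expect_error(readout(1:4, "middle_mean"),
               class = "molgat_middle_mean_error")
  # degenerate clamping on tiny graphs
  expect_equal(readout(7, "last_node"), 7)
  expect_equal(readout(7, "penultimate_node"), 7)
})

test_that("random readouts are seeded and in-range", {
  v <- c(10, 20, 30, 40)
  r1 <- readout(v, readout_strategy("random_node", seed = 5))
  r2 <- readout(v, readout_strategy("random_node", seed = 5))
  expect_identical(r1, r2)
  expect_true(r1 %in% v)
  m1 <- readout(v, readout_strategy("random_mean_5", seed = 5))
  expect_identical(m1, readout(v, readout_strategy("random_mean_5",
                                                   seed = 5)))
  expect_true(m1 >= min(v) && m1 <= max(v))
})

test_that("mean_pool readout equals the arithmetic mean of forward", {
  set.seed(4)
  model <- build_model(model_config(seed = 6))
  g <- random_graph(9L, 35L)
  p <- forward(model, g)
  expect_equal(readout(p, "mean_pool"), mean(p), tolerance = 1e-7)
})

test_that("layer type changes the parameter count, never the arity", {
  set.seed(5)
  g <- random_graph(5L, 35L)
  counts <- vapply(c("gat", "gatv2", "gcn"), function(type) {
    model <- build_model(model_config(layer_type = type, seed = 2))
    expect_length(forward(model, g), 5L)
    count_parameters(model)
  }, numeric(1))
  expect_equal(length(unique(counts)), 3L)
})
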