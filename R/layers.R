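# Graph convolution layers: forward and analytic backward passes.
#
# All layers operate on a disjoint-union batch (see as_graph_batch): a
# stacked feature matrix X and directed edge lists src -> dst that already
# contain both directions of every bond plus one self-loop per node, so
# attention is taken over neighbors-plus-self and the GCN normalization
# includes the self edge. Aggregations use rowsum(), which is C-level
# scatter-add; because every node has a self-loop, group labels cover
# 1..N and rowsum's sorted-group output aligns with node order.
#
# The attention softmax is stabilized per destination group by shifting
# with the group's self-loop logit (always a member of the group). If a
# shifted logit still overflows, the exact per-group maximum is computed
# as a fallback.

.leaky_slope <- 0.2

.leaky <- function(x) ifelse(x > 0, x, .leaky_slope * x)
.leaky_grad <- function(x) ifelse(x > 0, 1, .leaky_slope)

.rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

.rowsum_mat <- function(x, g, n) {
  out <- matrix(0, n, ncol(x))
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# Per-destination-group softmax of logits l along edges. self_pos[i] is the
# position in the edge list of node i's self-loop.
.edge_softmax <- function(l, dst, n, self_pos) {
  shift <- l[self_pos]
  w <- exp(l - shift[dst])
  if (any(!is.finite(w))) {
    mx <- vapply(split(l, dst), max, numeric(1))
    shift <- numeric(n)
    shift[as.integer(names(mx))] <- mx
    w <- exp(l - shift[dst])
  }
  denom <- .rowsum_vec(w, dst, n)
  w / denom[dst]
}

glorot <- function(fan_in, fan_out, nrow, ncol) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -s, s), nrow, ncol)
}

layer_init <- function(type, d_in, d_out) {
  switch(type,
    gat = list(type = "gat",
               W = glorot(d_in, d_out, d_in, d_out),
               a_src = as.numeric(glorot(1, d_out, d_out, 1)),
               a_dst = as.numeric(glorot(1, d_out, d_out, 1)),
               b = numeric(d_out)),
    gatv2 = list(type = "gatv2",
                 W_l = glorot(d_in, d_out, d_in, d_out),
                 W_r = glorot(d_in, d_out, d_in, d_out),
                 a = as.numeric(glorot(1, d_out, d_out, 1)),
                 b = numeric(d_out)),
    gcn = list(type = "gcn",
               W = glorot(d_in, d_out, d_in, d_out),
               b = numeric(d_out)),
    rlang::abort(paste0("unknown layer type '", type, "'; registry: ",
                        paste(names(.layer_registry), collapse = ", ")))
  )
}

# Closed-form trainable-parameter count per layer type.
.layer_registry <- list(
  gat = function(d_in, d_out) d_in * d_out + 3L * d_out,
  gatv2 = function(d_in, d_out) 2L * d_in * d_out + 2L * d_out,
  gcn = function(d_in, d_out) d_in * d_out + d_out)

layer_forward <- function(layer, X, batch, keep_cache = FALSE) {
  src <- batch$src
  dst <- batch$dst
  n <- batch$n_nodes
  self_pos <- (length(src) - n + 1L):length(src)
  switch(layer$type,
    gat = {
      Z <- X %*% layer$W
      s <- as.numeric(Z %*% layer$a_src)
      d <- as.numeric(Z %*% layer$a_dst)
      e <- s[src] + d[dst]
      alpha <- .edge_softmax(.leaky(e), dst, n, self_pos)
      H <- .rowsum_mat(alpha * Z[src, , drop = FALSE], dst, n)
      H <- sweep(H, 2L, layer$b, "+")
      cache <- if (keep_cache) list(X = X, Z = Z, e = e, alpha = alpha)
      list(H = H, cache = cache)
    },
    gatv2 = {
      Zl <- X %*% layer$W_l
      Zr <- X %*% layer$W_r
      hE <- Zl[src, , drop = FALSE] + Zr[dst, , drop = FALSE]
      tE <- .leaky(hE)
      l <- as.numeric(tE %*% layer$a)
      alpha <- .edge_softmax(l, dst, n, self_pos)
      H <- .rowsum_mat(alpha * Zl[src, , drop = FALSE], dst, n)
      H <- sweep(H, 2L, layer$b, "+")
      cache <- if (keep_cache) list(X = X, Zl = Zl, hE = hE, tE = tE,
                                    alpha = alpha)
      list(H = H, cache = cache)
    },
    gcn = {
      deg <- tabulate(dst, n)
      cE <- 1 / sqrt(deg[src] * deg[dst])
      Z <- X %*% layer$W
      H <- .rowsum_mat(cE * Z[src, , drop = FALSE], dst, n)
      H <- sweep(H, 2L, layer$b, "+")
      cache <- if (keep_cache) list(X = X, cE = cE)
      list(H = H, cache = cache)
    })
}

# Returns list(grads = named list like the layer's params, dX).
layer_backward <- function(layer, G, batch, cache) {
  src <- batch$src
  dst <- batch$dst
  n <- batch$n_nodes
  switch(layer$type,
    gat = {
      Zsrc <- cache$Z[src, , drop = FALSE]
      Gdst <- G[dst, , drop = FALSE]
      galpha <- rowSums(Gdst * Zsrc)
      dZ <- .rowsum_mat(cache$alpha * Gdst, src, n)
      S <- .rowsum_vec(cache$alpha * galpha, dst, n)
      dl <- cache$alpha * (galpha - S[dst])
      de <- dl * .leaky_grad(cache$e)
      ds <- .rowsum_vec(de, src, n)
      dd <- .rowsum_vec(de, dst, n)
      dZ <- dZ + outer(ds, layer$a_src) + outer(dd, layer$a_dst)
      list(grads = list(W = crossprod(cache$X, dZ),
                        a_src = as.numeric(crossprod(cache$Z, ds)),
                        a_dst = as.numeric(crossprod(cache$Z, dd)),
                        b = colSums(G)),
           dX = dZ %*% t(layer$W))
    },
    gatv2 = {
      Zlsrc <- cache$Zl[src, , drop = FALSE]
      Gdst <- G[dst, , drop = FALSE]
      galpha <- rowSums(Gdst * Zlsrc)
      dZl <- .rowsum_mat(cache$alpha * Gdst, src, n)
      S <- .rowsum_vec(cache$alpha * galpha, dst, n)
      dl <- cache$alpha * (galpha - S[dst])
      dh <- (dl * .leaky_grad(cache$hE)) *
        matrix(layer$a, nrow(cache$hE), length(layer$a), byrow = TRUE)
      dZl <- dZl + .rowsum_mat(dh, src, n)
      dZr <- .rowsum_mat(dh, dst, n)
      list(grads = list(W_l = crossprod(cache$X, dZl),
                        W_r = crossprod(cache$X, dZr),
                        a = as.numeric(crossprod(cache$tE, dl)),
                        b = colSums(G)),
           dX = dZl %*% t(layer$W_l) + dZr %*% t(layer$W_r))
    },
    gcn = {
      dZ <- .rowsum_mat(cache$cE * G[dst, , drop = FALSE], src, n)
      list(grads = list(W = crossprod(cache$X, dZ), b = colSums(G)),
           dX = dZ %*% t(layer$W))
    })
}
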