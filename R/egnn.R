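# E(n)-equivariant graph convolution core: forward pass, hand-written
# reverse-mode gradients, and Adam. Scalar node outputs are invariant to
# rigid motions because geometry enters only through squared inter-node
# distances; coordinate updates are equivariant by construction.

silu <- function(x) x / (1 + exp(-x))
dsilu <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}
relu <- function(x) pmax(x, 0)

addb <- function(M, b) sweep(M, 2, b, "+")

# scatter-add rows of `values` (n x d) into an L x d matrix at `index`
scatter_rows <- function(values, index, L) {
  out <- matrix(0, L, ncol(values))
  rs <- rowsum(values, index)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

# Parameter initialization. Transition layers feed ReLU (He scaling); the
# final linear of the coordinate MLP starts near zero so early coordinate
# updates are gentle.
init_head_params <- function(d_node, d_edge, config) {
  H <- config$hidden
  De <- if (d_edge > 0) config$edge_hidden else 0L
  p <- list(
    node_trans = list(W = rmat(d_node, config$node_dim, sqrt(2 / d_node)),
                      b = numeric(config$node_dim)),
    edge_trans = if (d_edge > 0) {
      list(W = rmat(d_edge, config$edge_hidden, sqrt(2 / d_edge)),
           b = numeric(config$edge_hidden))
    },
    in_proj = list(W = rmat(config$node_dim, H, sqrt(1 / config$node_dim)),
                   b = numeric(H)),
    layers = vector("list", config$n_layers),
    out_proj = list(W = rmat(H, config$n_bins, sqrt(1 / H)),
                    b = numeric(config$n_bins))
  )
  for (l in seq_len(config$n_layers)) {
    if (config$architecture == "egnn") {
      din <- 2L * H + 1L + De
      p$layers[[l]] <- list(
        We1 = rmat(din, H, sqrt(1 / din)), be1 = numeric(H),
        We2 = rmat(H, H, sqrt(1 / H)), be2 = numeric(H),
        Wx1 = rmat(H, H, sqrt(1 / H)), bx1 = numeric(H),
        Wx2 = rmat(H, 1, 1e-3),
        # the aggregation block sums messages over ~deg neighbors; its
        # input weights start small so early activations stay O(1)
        Wh1 = rmat(2L * H, H, sqrt(1 / (2 * H))) *
          rep(c(1, 0.2), each = H), bh1 = numeric(H),
        Wh2 = rmat(H, H, sqrt(1 / H)), bh2 = numeric(H)
      )
    } else {
      p$layers[[l]] <- list(
        W1 = rmat(H, H, sqrt(1 / H)), b1 = numeric(H),
        W2 = rmat(H, H, sqrt(1 / H)), b2 = numeric(H)
      )
    }
  }
  p
}

# One equivariant graph convolution. Messages m_ij = phi_e(h_i, h_j,
# ||x_i - x_j||^2, e_ij) along directed edges i -> j; coordinates move by
# the degree-normalized sum of (x_i - x_j) phi_x(m_ij); node states update
# as h_i <- phi_h(h_i, sum_j m_ij) with sum aggregation.
egcl_forward <- function(H, X, edges, Eattr, pl) {
  L <- nrow(H)
  src <- edges[, 1]
  dst <- edges[, 2]
  diff <- X[src, , drop = FALSE] - X[dst, , drop = FALSE]
  d2 <- rowSums(diff^2)
  # squared distances are fed on the scale of the squared contact cutoff
  # (16^2 A^2) so the message MLP sees O(1) inputs
  U <- cbind(H[src, , drop = FALSE], H[dst, , drop = FALSE], d2 / 256)
  if (!is.null(Eattr) && ncol(Eattr) > 0) U <- cbind(U, Eattr)
  A1 <- addb(U %*% pl$We1, pl$be1); Z1 <- silu(A1)
  A2 <- addb(Z1 %*% pl$We2, pl$be2); M <- silu(A2)
  P1 <- addb(M %*% pl$Wx1, pl$bx1); Q1 <- silu(P1)
  s <- as.numeric(Q1 %*% pl$Wx2)
  deg <- tabulate(src, nbins = L)
  cinv <- 1 / pmax(deg, 1)
  Xup <- X + cinv * scatter_rows(diff * s, src, L)
  agg <- scatter_rows(M, src, L)
  V <- cbind(H, agg)
  B1 <- addb(V %*% pl$Wh1, pl$bh1); R1 <- silu(B1)
  Hup <- addb(R1 %*% pl$Wh2, pl$bh2)
  list(H = Hup, X = Xup,
       cache = list(Hin = H, Xin = X, src = src, dst = dst, diff = diff,
                    d2 = d2, U = U, A1 = A1, Z1 = Z1, A2 = A2, M = M,
                    P1 = P1, Q1 = Q1, s = s, cinv = cinv, V = V, B1 = B1,
                    R1 = R1))
}

egcl_backward <- function(dHup, dXup, cache, pl, n_edge_attr) {
  L <- nrow(dHup)
  Hd <- ncol(dHup)
  src <- cache$src; dst <- cache$dst
  g <- list()
  # node MLP
  dR1 <- dHup %*% t(pl$Wh2)
  g$Wh2 <- crossprod(cache$R1, dHup); g$bh2 <- colSums(dHup)
  dB1 <- dR1 * dsilu(cache$B1)
  g$Wh1 <- crossprod(cache$V, dB1); g$bh1 <- colSums(dB1)
  dV <- dB1 %*% t(pl$Wh1)
  dH <- dV[, seq_len(Hd), drop = FALSE]
  dAgg <- dV[, Hd + seq_len(Hd), drop = FALSE]
  dM <- dAgg[src, , drop = FALSE]
  # coordinate path
  w <- cache$cinv[src]
  tmp <- dXup[src, , drop = FALSE] * w
  ds <- rowSums(tmp * cache$diff)
  ddiff <- tmp * cache$s
  dQ1 <- matrix(ds) %*% t(pl$Wx2)
  g$Wx2 <- crossprod(cache$Q1, matrix(ds))
  dP1 <- dQ1 * dsilu(cache$P1)
  g$Wx1 <- crossprod(cache$M, dP1); g$bx1 <- colSums(dP1)
  dM <- dM + dP1 %*% t(pl$Wx1)
  # edge MLP
  dA2 <- dM * dsilu(cache$A2)
  g$We2 <- crossprod(cache$Z1, dA2); g$be2 <- colSums(dA2)
  dZ1 <- dA2 %*% t(pl$We2)
  dA1 <- dZ1 * dsilu(cache$A1)
  g$We1 <- crossprod(cache$U, dA1); g$be1 <- colSums(dA1)
  dU <- dA1 %*% t(pl$We1)
  dd2 <- dU[, 2L * Hd + 1L] / 256
  ddiff <- ddiff + 2 * cache$diff * dd2
  dEattr <- if (n_edge_attr > 0) {
    dU[, 2L * Hd + 1L + seq_len(n_edge_attr), drop = FALSE]
  }
  dH <- dH +
    scatter_rows(dU[, seq_len(Hd), drop = FALSE], src, L) +
    scatter_rows(dU[, Hd + seq_len(Hd), drop = FALSE], dst, L)
  dX <- dXup + scatter_rows(ddiff, src, L) - scatter_rows(ddiff, dst, L)
  list(dH = dH, dX = dX, dEattr = dEattr, grads = g)
}

mlp_block_forward <- function(H, pl) {
  A1 <- addb(H %*% pl$W1, pl$b1); Z1 <- silu(A1)
  Hup <- addb(Z1 %*% pl$W2, pl$b2)
  list(H = Hup, cache = list(Hin = H, A1 = A1, Z1 = Z1))
}

mlp_block_backward <- function(dHup, cache, pl) {
  g <- list()
  dZ1 <- dHup %*% t(pl$W2)
  g$W2 <- crossprod(cache$Z1, dHup); g$b2 <- colSums(dHup)
  dA1 <- dZ1 * dsilu(cache$A1)
  g$W1 <- crossprod(cache$Hin, dA1); g$b1 <- colSums(dA1)
  list(dH = dA1 %*% t(pl$W1), grads = g)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Full head forward: learned node/edge transitions (ReLU), input projection,
# n_layers graph convolutions (or per-node MLP blocks), output projection,
# row softmax over the LDDT bins.
head_forward <- function(graph, params, config, keep_cache = FALSE) {
  Araw <- addb(graph$node_input %*% params$node_trans$W, params$node_trans$b)
  Hn0 <- relu(Araw)
  Eattr <- NULL
  Eraw <- NULL
  if (!is.null(params$edge_trans) && ncol(graph$edge_input) > 0 &&
      config$architecture == "egnn") {
    Eraw <- addb(graph$edge_input %*% params$edge_trans$W, params$edge_trans$b)
    Eattr <- relu(Eraw)
  }
  H <- addb(Hn0 %*% params$in_proj$W, params$in_proj$b)
  X <- graph$coords
  caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    if (config$architecture == "egnn") {
      st <- egcl_forward(H, X, graph$edges, Eattr, params$layers[[l]])
      H <- st$H; X <- st$X
    } else {
      st <- mlp_block_forward(H, params$layers[[l]])
      H <- st$H
    }
    caches[[l]] <- st$cache
  }
  logits <- addb(H %*% params$out_proj$W, params$out_proj$b)
  probs <- softmax_rows(logits)
  out <- list(probs = probs, logits = logits)
  if (keep_cache) {
    out$cache <- list(Araw = Araw, Hn0 = Hn0, Eraw = Eraw, Eattr = Eattr,
                      Hfinal = H, layers = caches)
  }
  out
}

head_backward <- function(dlogits, fwd, graph, params, config) {
  cache <- fwd$cache
  g <- list(layers = vector("list", config$n_layers))
  g$out_proj <- list(W = crossprod(cache$Hfinal, dlogits),
                     b = colSums(dlogits))
  dH <- dlogits %*% t(params$out_proj$W)
  dX <- matrix(0, nrow(graph$coords), 3)
  n_edge_attr <- if (is.null(cache$Eattr)) 0L else ncol(cache$Eattr)
  dEattr_total <- if (n_edge_attr > 0) {
    matrix(0, nrow(graph$edges), n_edge_attr)
  }
  for (l in rev(seq_len(config$n_layers))) {
    if (config$architecture == "egnn") {
      bk <- egcl_backward(dH, dX, cache$layers[[l]], params$layers[[l]],
                          n_edge_attr)
      dH <- bk$dH; dX <- bk$dX
      if (n_edge_attr > 0) dEattr_total <- dEattr_total + bk$dEattr
    } else {
      bk <- mlp_block_backward(dH, cache$layers[[l]], params$layers[[l]])
      dH <- bk$dH
    }
    g$layers[[l]] <- bk$grads
  }
  g$in_proj <- list(W = crossprod(cache$Hn0, dH), b = colSums(dH))
  dHn0 <- dH %*% t(params$in_proj$W)
  dAraw <- dHn0 * (cache$Araw > 0)
  g$node_trans <- list(W = crossprod(graph$node_input, dAraw),
                       b = colSums(dAraw))
  if (n_edge_attr > 0) {
    dEraw <- dEattr_total * (cache$Eraw > 0)
    g$edge_trans <- list(W = crossprod(graph$edge_input, dEraw),
                         b = colSums(dEraw))
  }
  g
}

# recursive map over parallel parameter trees; matched by name where named
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    keys <- if (!is.null(names(a))) names(a) else seq_along(a)
    for (nm in keys) {
      if (is.null(a[[nm]])) next
      out[[nm]] <- tree_map2(f, a[[nm]], if (is.null(b)) NULL else b[[nm]])
    }
    out
  } else {
    f(a, b)
  }
}

tree_zero <- function(a) tree_map2(function(x, ...) x * 0, a, NULL)

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, gr) beta1 * m + (1 - beta1) * gr,
                       state$m, grads)
  state$v <- tree_map2(function(v, gr) beta2 * v + (1 - beta2) * gr^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- tree_map2(function(m, ...) m / bc1, state$m, NULL)
  vh <- tree_map2(function(v, ...) v / bc2, state$v, NULL)
  upd <- tree_map2(function(m, v) m / (sqrt(v) + eps), mh, vh)
  # decoupled weight decay (applied to the parameters, not the gradient)
  params <- tree_map2(function(p, u) p * (1 - lr * weight_decay) - lr * u,
                      params, upd)
  list(params = params, state = state)
}
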