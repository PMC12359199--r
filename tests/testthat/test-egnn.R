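# independent per-edge reimplementation of one equivariant convolution,
# used as an oracle for the vectorized layer
naive_egcl <- function(H, X, edges, Eattr, pl) {
  silu <- function(x) x / (1 + exp(-x))
  L <- nrow(H)
  Hd <- ncol(H)
  msum <- matrix(0, L, Hd)
  xshift <- matrix(0, L, 3)
  deg <- rep(0, L)
  M <- matrix(0, nrow(edges), Hd)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    d2 <- sum((X[i, ] - X[j, ])^2)
    u <- c(H[i, ], H[j, ], d2 / 256)
    if (!is.null(Eattr) && ncol(Eattr) > 0) u <- c(u, Eattr[k, ])
    z1 <- silu(as.numeric(u %*% pl$We1) + pl$be1)
    m <- silu(as.numeric(z1 %*% pl$We2) + pl$be2)
    M[k, ] <- m
    q1 <- silu(as.numeric(m %*% pl$Wx1) + pl$bx1)
    s <- as.numeric(q1 %*% pl$Wx2)
    xshift[i, ] <- xshift[i, ] + (X[i, ] - X[j, ]) * s
    msum[i, ] <- msum[i, ] + m
    deg[i] <- deg[i] + 1
  }
  Xup <- X + xshift / pmax(deg, 1)
  Hup <- matrix(0, L, Hd)
  for (i in seq_len(L)) {
    v <- c(H[i, ], msum[i, ])
    r1 <- silu(as.numeric(v %*% pl$Wh1) + pl$bh1)
    Hup[i, ] <- as.numeric(r1 %*% pl$Wh2) + pl$bh2
  }
  list(H = Hup, X = Xup)
}

layer_params <- function(Hd, De, seed = 1) {
  set.seed(seed)
  r <- function(a, b) matrix(rnorm(a * b, sd = 0.2), a, b)
  list(We1 = r(2 * Hd + 1 + De, Hd), be1 = rnorm(Hd, sd = 0.1),
       We2 = r(Hd, Hd), be2 = rnorm(Hd, sd = 0.1),
       Wx1 = r(Hd, Hd), bx1 = rnorm(Hd, sd = 0.1),
       Wx2 = r(Hd, 1),
       Wh1 = r(2 * Hd, Hd), bh1 = rnorm(Hd, sd = 0.1),
       Wh2 = r(Hd, Hd), bh2 = rnorm(Hd, sd = 0.1))
}

test_that("the vectorized convolution matches a per-edge oracle", {
  set.seed(2)
  for (rep in 1:3) {
    L <- sample(4:9, 1)
    Hd <- 5
    De <- if (rep == 3) 0 else 4
    X <- matrix(rnorm(L * 3, sd = 6), L, 3)
    H <- matrix(rnorm(L * Hd), L, Hd)
    edges <- build_edges(X)
    Eattr <- if (De > 0) matrix(rnorm(nrow(edges) * De), ncol = De)
    pl <- layer_params(Hd, De, seed = rep)
    got <- egnnqa:::egcl_forward(H, X, edges, Eattr, pl)
    want <- naive_egcl(H, X, edges, Eattr, pl)
    expect_equal(got$H, want$H, tolerance = 1e-12)
    expect_equal(got$X, want$X, tolerance = 1e-12)
  }
})

test_that("a 2-node convolution matches scalar hand computation", {
  # hidden width 1 so every map is scalar arithmetic
  silu <- function(x) x / (1 + exp(-x))
  pl <- list(We1 = matrix(c(0.5, -0.3, 0.2), 3, 1), be1 = 0.1,
             We2 = matrix(0.7), be2 = -0.2,
             Wx1 = matrix(0.4), bx1 = 0.0, Wx2 = matrix(0.9),
             Wh1 = matrix(c(0.6, -0.5), 2, 1), bh1 = 0.05,
             Wh2 = matrix(1.1), bh2 = 0.3)
  H <- matrix(c(0.2, -0.4), 2, 1)
  X <- rbind(c(0, 0, 0), c(3, 0, 0))
  edges <- rbind(c(1L, 2L), c(2L, 1L))
  got <- egnnqa:::egcl_forward(H, X, edges, NULL, pl)
  # edge 1->2: u = (h1, h2, 9/256)
  m12 <- silu(0.7 * silu(0.5 * 0.2 - 0.3 * (-0.4) + 0.2 * 9 / 256 + 0.1) - 0.2)
  m21 <- silu(0.7 * silu(0.5 * (-0.4) - 0.3 * 0.2 + 0.2 * 9 / 256 + 0.1) - 0.2)
  s12 <- silu(0.4 * m12) * 0.9
  s21 <- silu(0.4 * m21) * 0.9
  expect_equal(got$X[1, 1], 0 + (0 - 3) * s12, tolerance = 1e-12)
  expect_equal(got$X[2, 1], 3 + (3 - 0) * s21, tolerance = 1e-12)
  h1 <- 1.1 * silu(0.6 * 0.2 - 0.5 * m12 + 0.05) + 0.3
  h2 <- 1.1 * silu(0.6 * (-0.4) - 0.5 * m21 + 0.05) + 0.3
  expect_equal(got$H[, 1], c(h1, h2), tolerance = 1e-12)
})

test_that("zeroed parameters leave features on the bias path and coords fixed", {
  Hd <- 4
  pl <- layer_params(Hd, 0, seed = 9)
  pl <- lapply(pl, function(m) m * 0)
  pl$bh2 <- c(1, 2, 3, 4)
  X <- matrix(rnorm(12, sd = 5), 4, 3)
  H <- matrix(rnorm(16), 4, Hd)
  got <- egnnqa:::egcl_forward(H, X, build_edges(X), NULL, pl)
  expect_equal(got$X, X)  # phi_x is identically zero
  expect_true(all(abs(sweep(got$H, 2, c(1, 2, 3, 4))) < 1e-12))
})

test_that("the convolution is E(3)-equivariant", {
  set.seed(12)
  Hd <- 6
  L <- 7
  X <- matrix(rnorm(L * 3, sd = 6), L, 3)
  H <- matrix(rnorm(L * Hd), L, Hd)
  edges <- build_edges(X)
  Eattr <- matrix(rnorm(nrow(edges) * 3), ncol = 3)
  pl <- layer_params(Hd, 3, seed = 5)
  base <- egnnqa:::egcl_forward(H, X, edges, Eattr, pl)
  R <- random_rotation()
  t <- rnorm(3, sd = 10)
  moved <- egnnqa:::egcl_forward(H, sweep(X %*% t(R), 2, t, "+"), edges,
                                 Eattr, pl)
  expect_equal(moved$H, base$H, tolerance = 1e-9)
  expect_equal(moved$X, sweep(base$X %*% t(R), 2, t, "+"), tolerance = 1e-9)
})

test_that("bin readout, weights and loss obey their algebra", {
  # uniform distribution reads out as 50, one-hot as the bin center
  uni <- matrix(1 / 50, 1, 50)
  expect_equal(bins_to_plddt(uni), 50)
  hot49 <- matrix(0, 1, 50); hot49[1, 50] <- 1
  expect_equal(bins_to_plddt(hot49), 99)
  hot0 <- matrix(0, 1, 50); hot0[1, 1] <- 1
  expect_equal(bins_to_plddt(hot0), 1)

  # weights: single-bin data zeroes that bin's weight
  w <- compute_bin_weights(rep(99, 10))
  expect_equal(w[50], 0)
  expect_equal(w[-50], rep(1, 49), ignore_attr = TRUE)
  w2 <- compute_bin_weights(c(rep(10, 5), rep(90, 5)))
  expect_equal(w2[lddt_bin(10)], 0.5)
  expect_equal(w2[lddt_bin(90)], 0.5)
  expect_equal(sum(compute_bin_weights(runif(100, 0, 100))), 49)
  expect_equal(lddt_bin(100), 50L)  # top edge closed

  # loss: perfect one-hot prediction is ~0
  true <- c(10, 90)
  P <- matrix(1e-12, 2, 50)
  P[cbind(1:2, lddt_bin(true))] <- 1
  P <- P / rowSums(P)
  expect_lt(weighted_bin_loss(P, true, compute_bin_weights(true)), 1e-4)
  # uniform prediction gives log 50 for any weights
  U <- matrix(1 / 50, 2, 50)
  expect_equal(weighted_bin_loss(U, true, rep(1, 50)), log(50))
  expect_equal(weighted_bin_loss(U, true, compute_bin_weights(runif(50, 0, 100))),
               log(50))
  # zero-weight residues are excluded exactly
  w3 <- rep(0, 50); w3[lddt_bin(10)] <- 1
  P2 <- matrix(runif(100), 2, 50); P2 <- P2 / rowSums(P2)
  expect_equal(weighted_bin_loss(P2, true, w3), -log(P2[1, lddt_bin(10)]))
  # uniform weights reduce to plain mean cross-entropy
  ce <- mean(-log(P2[cbind(1:2, lddt_bin(true))]))
  expect_equal(weighted_bin_loss(P2, true, rep(1, 50)), ce)
})

test_that("head predictions are rigid-motion invariant and permutation equivariant", {
  set.seed(33)
  rec <- make_dataset(1, length_range = c(14, 14), seed = 77)[[1]]
  h <- qa_head(list(list(graph = rec$graph, lddt = rec$lddt)),
               epochs = 2, seed = 3)
  base <- predict(h, rec$graph, type = "bins")
  expect_equal(rowSums(base), rep(1, nrow(base)), tolerance = 1e-6)
  for (k in 1:3) {
    g2 <- rec$graph
    R <- random_rotation()
    g2$coords <- sweep(g2$coords %*% t(R), 2, rnorm(3, sd = 15), "+")
    expect_lt(max(abs(predict(h, g2, type = "bins") - base)), 1e-4)
    expect_lt(max(abs(predict(h, g2) - predict(h, rec$graph))), 1e-4)
  }
  perm <- sample(nrow(rec$graph$coords))
  gp <- permute_graph(rec$graph, perm)
  expect_equal(predict(h, gp, type = "bins"), base[perm, ], tolerance = 1e-9)
})

test_that("training reduces the loss and is deterministic in the seed", {
  recs <- make_dataset(3, length_range = c(12, 16), seed = 55)
  train <- as_training_set(recs)
  h1 <- qa_head(train, epochs = 8, seed = 4)
  expect_lt(h1$loss_trace[8], h1$loss_trace[1])
  h2 <- qa_head(train, epochs = 8, seed = 4)
  expect_identical(h1$loss_trace, h2$loss_trace)
  expect_equal(coef(h1)$out_proj$W, coef(h2)$out_proj$W)
  # a different seed gives a different trajectory
  h3 <- qa_head(train, epochs = 8, seed = 5)
  expect_false(identical(h1$loss_trace, h3$loss_trace))
})

test_that("fit object methods behave like a standard model fit", {
  recs <- make_dataset(2, length_range = c(12, 14), seed = 66)
  h <- qa_head(as_training_set(recs), epochs = 3, seed = 1)
  expect_output(print(h), "egnn")
  s <- summary(h)
  expect_s3_class(s, "summary.qa_head")
  expect_length(s$training_model_error, 2)
  f <- fitted(h)
  expect_length(f, 2)
  expect_true(all(f[[1]] >= 1 & f[[1]] <= 99))
  r <- residuals(h)
  expect_equal(unname(f[[1]] - egnnqa:::.true_vector(recs[[1]]$graph,
                                                     recs[[1]]$lddt)),
               unname(r[[1]]))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path); plot(h); grDevices::dev.off()
  expect_true(file.exists(path))
  # predict rejects mismatched feature widths
  g_bad <- recs[[1]]$graph
  g_bad$node_input <- g_bad$node_input[, 1:10]
  expect_error(predict(h, g_bad), "does not match")
})

test_that("non-finite training loss aborts with a diagnostic", {
  recs <- make_dataset(1, length_range = c(12, 12), seed = 21)
  expect_error(
    qa_head(as_training_set(recs), epochs = 2, seed = 1,
            learning_rate = 1e6),
    "non-finite|missing value", ignore.case = TRUE)
})
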