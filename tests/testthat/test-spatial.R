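spatial_params <- function(n_features = 8, n_heads = 2, n_nodes = 4,
                           cheb_order = 2, seed = 1) {
  cfg <- tiny_config(n_features = n_features, n_heads = n_heads,
                     cheb_order = cheb_order, seed = seed)
  build_model(cfg, n_nodes)$params$blocks[[1]]$spatial
}

test_that("positional embedding has the contracted 4-D shape and is linear", {
  cfg <- tiny_config(n_features = 8)
  coh <- tiny_cohort(n_per_class = 2, n_nodes = 4, L = 20)
  b <- assemble_batches(coh$records, 5, 1, 50, seed = 1, cheb_order = 2)[[1]]
  p <- build_model(cfg, 4)$params$blocks[[1]]$spatial
  emb <- embed_positions(b$series, b$adjacency, p, starts = b$start)
  expect_equal(dim(emb), c(dim(b$series), 8))
  expect_true(all(is.finite(emb)))
  # zero input with zero convolution weights gives zero output
  p0 <- p
  p0$embed_W[] <- 0; p0$embed_b[] <- 0
  z <- embed_positions(array(0, dim(b$series)), b$adjacency, p0, starts = b$start)
  expect_equal(max(abs(z)), 0)
  # doubling the 1x1 convolution weights (zero bias) doubles the activations
  pa <- p; pa$embed_b[] <- 0; pa$dw_W[] <- 0; pa$dw_W[2, ] <- 1  # identity tap
  pb <- pa; pb$embed_W <- 2 * pa$embed_W
  e1 <- embed_positions(b$series, b$adjacency, pa, starts = b$start)
  e2 <- embed_positions(b$series, b$adjacency, pb, starts = b$start)
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
})

test_that("identical node features give uniform attention and identical outputs", {
  p <- spatial_params(n_features = 8, n_nodes = 5)
  x <- rand_tensor(1, 3, 1, 8, seed = 4)
  x <- array(rep(x, each = 1), c(1, 3, 5, 8))
  for (n in 1:5) x[, , n, ] <- x[, , 1, ]
  out <- spatial_attention(x, p, n_heads = 2)
  expect_equal(max(abs(out$maps - 0.2)), 0, tolerance = 1e-12)
  for (n in 2:5) expect_equal(out$features[, , n, ], out$features[, , 1, ])
})

test_that("a single node attends to itself with weight exactly 1", {
  p <- spatial_params(n_features = 8, n_nodes = 1)
  x <- rand_tensor(2, 3, 1, 8, seed = 5)
  out <- spatial_attention(x, p, n_heads = 2)
  expect_equal(max(abs(out$maps - 1)), 0, tolerance = 1e-14)
})

test_that("spatial attention matches the per-query loop oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    N <- sample(2:6, 1)
    T_ <- sample(2:5, 1)
    p <- spatial_params(n_features = 6, n_heads = 2, n_nodes = N, seed = seed)
    x <- rand_tensor(1, T_, N, 6, seed = 100 + seed)
    got <- spatial_attention(x, p, n_heads = 2)
    want <- oracle_spatial_attention(x, p, 2)
    expect_lt(max(abs(got$features - want)), 1e-5)
    expect_lt(max(abs(apply(got$maps, c(1, 2, 3, 4), sum) - 1)), 1e-6)
    expect_true(all(got$maps > 0 & got$maps < 1 | N == 1))
  }
})

test_that("attention scale option switches between sqrt(d) and d", {
  p <- spatial_params(n_features = 8, n_nodes = 4)
  x <- rand_tensor(1, 2, 4, 8, seed = 6)
  a <- spatial_attention(x, p, 2, attention_scale = "sqrt_d")
  b <- spatial_attention(x, p, 2, attention_scale = "d")
  expect_false(isTRUE(all.equal(a$maps, b$maps)))
  expect_lt(max(abs(b$features - oracle_spatial_attention(x, p, 2, "d"))), 1e-5)
})

test_that("non-finite attention input is rejected before the softmax", {
  p <- spatial_params()
  x <- rand_tensor(1, 2, 4, 8)
  x[1, 1, 1, 1] <- NaN
  expect_error(spatial_attention(x, p, 2), "non-finite")
})

test_that("chebyshev GCN matches the dense explicit-polynomial oracle", {
  for (K in 1:4) {
    for (seed in 1:5) {
      set.seed(seed)
      N <- sample(3:8, 1)
      net <- rand_network(N, seed = 50 + seed)
      p <- spatial_params(n_features = 6, n_nodes = N, cheb_order = K,
                          seed = seed)
      x <- rand_tensor(2, 3, N, 6, seed = 200 + seed)
      got <- chebyshev_gcn(x, net, p, K)
      want <- oracle_cheb_gcn(x, net$adjacency, p$theta[seq_len(K)])
      expect_lt(max(abs(got - want)), 1e-8)
    }
  }
})

test_that("K = 1 GCN ignores the graph entirely", {
  p <- spatial_params(n_features = 6, n_nodes = 5, cheb_order = 1)
  x <- rand_tensor(1, 2, 5, 6, seed = 8)
  a <- chebyshev_gcn(x, rand_network(5, seed = 1), p, 1)
  b <- chebyshev_gcn(x, diag(5), p, 1)
  expect_equal(a, b)
  # and equals ReLU(X Theta_0) node by node
  want <- oracle_cheb_gcn(x, diag(5), p$theta[1])
  expect_lt(max(abs(a - want)), 1e-10)
})

test_that("chebyshev GCN is node-permutation equivariant", {
  N <- 6
  net <- rand_network(N, seed = 9)
  p <- spatial_params(n_features = 6, n_nodes = N, cheb_order = 3)
  x <- rand_tensor(2, 3, N, 6, seed = 10)
  perm <- c(4, 1, 6, 2, 5, 3)
  a <- chebyshev_gcn(x, net$adjacency, p, 3)
  b <- chebyshev_gcn(x[, , perm, , drop = FALSE], net$adjacency[perm, perm], p, 3)
  expect_equal(b, a[, , perm, , drop = FALSE], tolerance = 1e-10)
})

test_that("gate output is a convex combination of its inputs", {
  p <- spatial_params(n_features = 8, n_nodes = 4)
  u <- rand_tensor(2, 3, 4, 8, seed = 11)
  g <- rand_tensor(2, 3, 4, 8, seed = 12)
  y <- gate_fuse(u, g, p)
  expect_true(all(y >= pmin(u, g) - 1e-12 & y <= pmax(u, g) + 1e-12))
  # equal inputs pass through unchanged
  expect_equal(gate_fuse(u, u, p), u, tolerance = 1e-12)
  # zero gate weights give the elementwise mean
  p0 <- p; p0$gate_W[] <- 0; p0$gate_b[] <- 0
  expect_equal(gate_fuse(u, g, p0), (u + g) / 2, tolerance = 1e-12)
  expect_error(gate_fuse(u, g[, , 1:2, , drop = FALSE], p), "identical shapes")
})

test_that("spatial block output keeps the embedded shape and is deterministic", {
  cfg <- tiny_config(n_features = 8, cheb_order = 2)
  coh <- tiny_cohort(n_per_class = 2, n_nodes = 4, L = 20)
  b <- assemble_batches(coh$records, 5, 1, 50, seed = 1, cheb_order = 2)[[1]]
  p <- build_model(cfg, 4)$params$blocks[[1]]$spatial
  out1 <- spatial_block_forward(b$series, b$adjacency, p, starts = b$start)
  out2 <- spatial_block_forward(b$series, b$adjacency, p, starts = b$start)
  expect_equal(dim(out1$features), c(dim(b$series), 8))
  expect_identical(out1$features, out2$features)
  expect_equal(dim(out1$maps), c(2, dim(b$series)[1], 5, 4, 4))
})

test_that("the whole spatial block is jointly node-relabeling equivariant", {
  # relabeling nodes permutes the inputs, the adjacency, and the rows of the
  # 1x1 convolution that read the connectomic encoding
  cfg <- tiny_config(n_features = 8, cheb_order = 2)
  N <- 5
  coh <- tiny_cohort(n_per_class = 1, n_nodes = N, L = 20)
  b <- assemble_batches(coh$records, 5, 1, 50, seed = 1, cheb_order = 2)[[1]]
  p <- build_model(cfg, N)$params$blocks[[1]]$spatial
  perm <- c(3, 5, 1, 4, 2)
  pperm <- p
  senc_rows <- 1 + 8 + seq_len(N)  # signal + temporal enc + spatial enc block
  pperm$embed_W[senc_rows, ] <- p$embed_W[senc_rows[perm], ]
  a <- spatial_block_forward(b$series, b$adjacency, p, starts = b$start)
  bperm <- spatial_block_forward(b$series[, , perm, drop = FALSE],
                                 b$adjacency[perm, perm, , drop = FALSE],
                                 pperm, starts = b$start)
  expect_equal(bperm$features, a$features[, , perm, , drop = FALSE],
               tolerance = 1e-10)
})
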