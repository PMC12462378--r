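# independent oracles for every layer of the network

test_that("normalised propagation matches dense D^{-1/2} A D^{-1/2}", {
  expect_equal(normalized_propagation(matrix(TRUE, 1, 1)), matrix(1, 1, 1))
  # 3-clique with self-loops: every entry 1/3, rows sum to 1
  P3 <- normalized_propagation(matrix(TRUE, 3, 3))
  expect_true(all(abs(P3 - 1 / 3) < 1e-15))
  expect_equal(rowSums(P3), rep(1, 3))
  set.seed(12)
  A <- build_adjacency(random_coords(8))$adjacency
  P <- normalized_propagation(A)
  Dm <- diag(1 / sqrt(rowSums(A * 1)))
  expect_close(P, Dm %*% (A * 1) %*% Dm, 1e-12)
  expect_equal(P, t(P))
})

test_that("beta schedule: limits, symmetry point, monotonicity, printed form", {
  expect_equal(beta_schedule(1:5, 0), rep(0, 5))
  expect_equal(beta_schedule(3, 3), log(2))
  bs <- beta_schedule(1:4, 0.5)
  expect_true(all(diff(bs) < 0))
  expect_equal(bs, log(0.5 / (1:4) + 1))
  expect_equal(beta_schedule(1:4, 0.5, form = "printed"), log(0.5 * (1:4) + 1))
  expect_true(all(diff(beta_schedule(1:4, 0.5, form = "printed")) > 0))
  expect_error(beta_schedule(0, 1))
})

test_that("graph pooling keeps top-k scores with gating and induced adjacency", {
  # rho = 1: identity up to the sigmoid gate
  H <- matrix(c(3, 1, 2, 1), 4, 1)
  A <- matrix(TRUE, 4, 4)
  out <- graph_pool(H, A, pool_w = matrix(1, 1, 1), pool_ratio = 1)
  expect_equal(out$idx, 1:4)
  expect_identical(out$adjacency, A)
  expect_close(out$H, H * (1 / (1 + exp(-c(3, 1, 2, 1)))), 1e-12)
  # scores (3, 1, 2, 1), rho = 0.5 -> positions 1 and 3 kept
  out2 <- graph_pool(H, A, matrix(1, 1, 1), 0.5)
  expect_equal(out2$idx, c(1L, 3L))
  # tie rule: equal scores -> lower index wins
  out3 <- graph_pool(matrix(1, 4, 1), A, matrix(1, 1, 1), 0.5)
  expect_equal(out3$idx, c(1L, 2L))
  # rho n < 1 floors at one node
  out4 <- graph_pool(H[1:2, , drop = FALSE], A[1:2, 1:2], matrix(1, 1, 1), 0.1)
  expect_equal(length(out4$idx), 1L)
  # induced adjacency equals brute-force subsetting on a random graph
  set.seed(13)
  g <- random_graph(10, d = 6)
  H10 <- matrix(rnorm(60), 10)
  w <- matrix(rnorm(6), 6, 1)
  out5 <- graph_pool(H10, g$adjacency, w, 0.4)
  s <- as.vector(H10 %*% w) / sqrt(sum(w^2))
  idx <- sort(order(-s)[1:4])
  expect_equal(out5$idx, idx)
  expect_identical(out5$adjacency, g$adjacency[idx, idx])
  expect_true(all(diag(out5$adjacency)))
  expect_close(out5$H, H10[idx, ] * (1 / (1 + exp(-s[idx]))), 1e-12)
})

test_that("subgraph convolution layer: limit identities and dense oracle", {
  set.seed(14)
  n <- 5; d <- 4
  A <- build_adjacency(random_coords(n))$adjacency
  P <- normalized_propagation(A)
  H <- matrix(rnorm(n * d), n); H0 <- matrix(rnorm(n * d), n)
  W <- matrix(rnorm(d * d), d)
  # alpha = 0, beta = 0 -> relu(P H)
  expect_close(subgraph_conv_layer(H, H0, P, W, 0, 0), pmax(P %*% H, 0), 1e-12)
  # alpha = 1 -> relu(H0((1-b)I + bW)), independent of H
  b <- 0.37
  expect_close(subgraph_conv_layer(H, H0, P, W, 1, b),
               pmax(H0 %*% ((1 - b) * diag(d) + b * W), 0), 1e-12)
  expect_equal(subgraph_conv_layer(H, H0, P, W, 1, b),
               subgraph_conv_layer(matrix(9, n, d), H0, P, W, 1, b))
  # general case vs step-by-step dense evaluation
  for (rep in 1:20) {
    al <- runif(1); be <- runif(1)
    H1 <- matrix(rnorm(n * d), n); H01 <- matrix(rnorm(n * d), n)
    W1 <- matrix(rnorm(d * d), d)
    oracle <- pmax(((1 - al) * P %*% H1 + al * H01) %*%
                     ((1 - be) * diag(d) + be * W1), 0)
    expect_close(subgraph_conv_layer(H1, H01, P, W1, al, be), oracle, 1e-10)
  }
})

test_that("edge-aware attention: degenerate cases and double-loop oracle", {
  set.seed(15)
  d <- 4; de <- 3
  mk_params <- function() list(Wh = matrix(rnorm(d * d), d),
                               a_src = matrix(rnorm(d), d, 1),
                               a_dst = matrix(rnorm(d), d, 1),
                               We = matrix(rnorm(2 * de), 2, de),
                               a_edge = matrix(rnorm(de), de, 1))
  # isolated self-looped node: coefficient 1, output Wh h
  p <- mk_params()
  h1 <- matrix(rnorm(d), 1)
  out1 <- agat_attention_layer(h1, matrix(TRUE, 1, 1), rbind(1L, 1L),
                               matrix(0, 1, 2), p$Wh, p$a_src, p$a_dst,
                               p$We, p$a_edge)
  expect_equal(out1$coef[1, 1], 1)
  expect_close(out1$H, h1 %*% p$Wh, 1e-12)
  # identical neighbours and identical edge features -> uniform 1/|N(i)|
  n <- 4
  Hsame <- matrix(rep(rnorm(d), each = n), n)
  adj <- matrix(TRUE, n, n)
  ei <- rbind(rep(1:n, each = n), rep(1:n, n))
  ef_same <- matrix(rep(c(0.3, 0.1), each = n * n), n * n)
  outu <- agat_attention_layer(Hsame, adj, ei, ef_same, p$Wh, p$a_src,
                               p$a_dst, p$We, p$a_edge)
  expect_true(all(abs(outu$coef - 1 / n) < 1e-12))
  # random graph vs explicit double loop
  for (rep in 1:10) {
    g <- random_graph(6, d = d)
    H <- matrix(rnorm(6 * d), 6)
    p <- mk_params()
    out <- agat_attention_layer(H, g$adjacency, g$edge_index, g$edge_features,
                                p$Wh, p$a_src, p$a_dst, p$We, p$a_edge, 0.2)
    expect_close(rowSums(out$coef), rep(1, 6), 1e-12)
    WhH <- H %*% p$Wh
    edge_scalar <- function(i, j) {
      e <- which(g$edge_index[1, ] == i & g$edge_index[2, ] == j)
      sum((g$edge_features[e, , drop = FALSE] %*% p$We) * t(p$a_edge))
    }
    for (i in 1:6) {
      nb <- which(g$adjacency[i, ])
      logits <- vapply(nb, function(j) {
        z <- sum(WhH[i, ] * p$a_src) + sum(WhH[j, ] * p$a_dst) + edge_scalar(i, j)
        if (z > 0) z else 0.2 * z
      }, 0)
      co <- exp(logits - max(logits)); co <- co / sum(co)
      expect_close(out$coef[i, nb], co, 1e-10)
      expect_close(out$H[i, ], as.vector(co %*% WhH[nb, , drop = FALSE]), 1e-10)
    }
  }
  # missing edge feature for an adjacent pair is refused
  g <- random_graph(5, d = d)
  expect_error(agat_attention_layer(matrix(rnorm(5 * d), 5), g$adjacency,
                                    g$edge_index[, -1], g$edge_features[-1, ],
                                    p$Wh, p$a_src, p$a_dst, p$We, p$a_edge),
               "missing edge feature")
})

test_that("identity-mapping combination layer: limits, oracle, shape guard", {
  set.seed(16)
  n <- 5; d <- 4
  H_in <- matrix(rnorm(n * d), n); H0 <- matrix(rnorm(n * d), n)
  W <- matrix(rnorm(2 * d * d), 2 * d)
  expect_close(gcnii_layer(H_in, H0, W, 0, 0), pmax(H_in, 0), 1e-12)
  expect_close(gcnii_layer(H_in, H0, W, 1, 0), pmax(H0, 0), 1e-12)
  for (rep in 1:20) {
    al <- runif(1); be <- runif(1)
    Hr <- matrix(rnorm(n * d), n); H0r <- matrix(rnorm(n * d), n)
    Wr <- matrix(rnorm(2 * d * d), 2 * d)
    oracle <- pmax((1 - be) * ((1 - al) * Hr + al * H0r) +
                     be * (cbind(Hr, H0r) %*% Wr), 0)
    expect_close(gcnii_layer(Hr, H0r, Wr, al, be), oracle, 1e-10)
  }
  expect_error(gcnii_layer(H_in, H0, matrix(0, d, d), 0.5, 0.5),
               "W must be \\[2d x d\\]")
})

test_that("attention fusion: degenerate cases and brute-force oracle", {
  set.seed(17)
  # n = 1: softmax of a scalar is 1
  hs <- matrix(rnorm(3), 1); ha <- matrix(rnorm(5), 1)
  expect_close(att_fusion(hs, ha)$H, ha, 1e-12)
  # all-zero queries -> uniform attention -> column means
  Ha <- matrix(rnorm(40), 10)
  outz <- att_fusion(matrix(0, 10, 8), Ha)
  expect_close(outz$H, matrix(rep(colMeans(Ha), each = 10), 10), 1e-12)
  # random instances vs double-loop scaled dot-product
  for (rep in 1:10) {
    n <- sample(2:12, 1)
    Hs <- matrix(rnorm(n * 8), n); Hg <- matrix(rnorm(n * 16), n)
    out <- att_fusion(Hs, Hg)
    oracle <- matrix(0, n, 16)
    for (i in 1:n) {
      sc <- vapply(1:n, function(j) sum(Hs[i, ] * Hs[j, ]) / sqrt(8), 0)
      co <- exp(sc - max(sc)); co <- co / sum(co)
      oracle[i, ] <- as.vector(co %*% Hg)
    }
    expect_close(out$H, oracle, 1e-8)
    expect_close(rowSums(out$coef), rep(1, n), 1e-12)
  }
  expect_error(att_fusion(matrix(0, 3, 2), matrix(0, 4, 2)), "row-count mismatch")
})

test_that("MLP head emits row-stochastic probabilities and thresholded calls", {
  set.seed(18)
  cfg <- ppis_config(d_hidden = 6, seed = 3)
  params <- init_parameters(10, cfg)
  H1 <- matrix(rnorm(42), 7); H2 <- matrix(rnorm(42), 7)
  pr <- mlp_head(H1, H2, params)
  expect_close(rowSums(pr$probs), rep(1, 7), 1e-6)
  expect_identical(pr$calls, as.integer(pr$probs[, 2] >= 0.5))
  # zero weights -> maximal uncertainty
  zero <- lapply(params, function(p) p * 0)
  przero <- mlp_head(H1, H2, zero)
  expect_true(all(abs(przero$probs - 0.5) < 1e-12))
  expect_true(mlp_head(matrix(0, 1, 6), matrix(0, 1, 6),
                       within(zero, mlp_b3 <- matrix(c(-1, 1), 1)))$calls == 1L)
})

test_that("forward pass: determinism, degenerate sizes, finiteness", {
  set.seed(19)
  cfg <- ppis_config(d_hidden = 8, seed = 5)
  for (n in c(1, 2, 10, 60)) {
    g <- random_graph(n, d = 6)
    params <- init_parameters(6, cfg)
    p1 <- ppis_forward(g, params, cfg)
    p2 <- ppis_forward(g, params, cfg)
    expect_identical(p1$probs, p2$probs)
    expect_true(all(is.finite(p1$probs)))
    expect_close(rowSums(p1$probs), rep(1, n), 1e-6)
  }
})

test_that("forward pass is equivariant to residue relabelling", {
  set.seed(20)
  g <- random_graph(15, d = 6)
  cfg <- ppis_config(d_hidden = 8, seed = 5)
  params <- init_parameters(6, cfg)
  base <- ppis_forward(g, params, cfg)$probs
  perm <- sample(15)
  gp <- permute_graph(g, perm)
  permd <- ppis_forward(gp, params, cfg)$probs
  expect_close(permd, base[perm, ], 1e-5)
})

test_that("every parameter receives a nonzero gradient", {
  set.seed(22)
  g <- random_graph(12, d = 6)
  cfg <- ppis_config(d_hidden = 8, dropout = 0, seed = 7)
  params <- init_parameters(6, cfg)
  tp <- ppi("ad_tape")()
  leaves <- lapply(params, function(p) ppi("ad_param")(tp, p))
  fw <- ppi("tape_forward")(tp, g, leaves, cfg, FALSE)
  losses <- ppi("tape_total_loss")(tp, fw$probs, g$labels, sol_config())
  ppi("ad_backward")(tp, losses$total)
  for (nm in names(params)) {
    expect_false(is.null(leaves[[nm]]$grad), label = sprintf("grad of %s", nm))
    expect_gt(max(abs(leaves[[nm]]$grad)), 0)
  }
})
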