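# Attention layer, pooling, full model, parameter counting.

test_that("attention rows are a probability distribution over incoming edges", {
  set.seed(1)
  g <- random_graph(6, 10, 4, p_edge = 0.6)
  cfg <- egat_config(hidden_dim = 8, n_heads = 2, head_dims = c(6, 6, 5))
  p <- init_egat_params(cfg, 10, 4)
  lay <- egat_layer_forward(g$node_features, g$edge_index, g$edge_features,
                            p$layers[[1]])
  sums <- rowsum(lay$alpha, lay$dst)
  expect_true(max(abs(sums - 1)) < 1e-7)
  expect_true(all(lay$alpha >= 0))
})

test_that("a single-node graph attends only to itself", {
  set.seed(2)
  X <- matrix(rnorm(10), 1, 10)
  cfg <- egat_config(hidden_dim = 8, n_heads = 2, head_dims = c(6, 6, 5))
  p <- init_egat_params(cfg, 10, 4)
  lay <- egat_layer_forward(X, matrix(integer(0), 0, 2), matrix(0, 0, 4),
                            p$layers[[1]])
  expect_equal(as.numeric(lay$alpha), c(1, 1))
  # h' = ELU(W h) with alpha = 1
  Z <- X %*% p$layers[[1]]$W
  expect_equal(lay$out, elu(Z), tolerance = 1e-12)
})

test_that("layer output matches the brute-force dense oracle", {
  set.seed(3)
  cfg <- egat_config(hidden_dim = 12, n_heads = 3, head_dims = c(8, 6, 5))
  p <- init_egat_params(cfg, 7, 4)
  for (trial in 1:10) {
    g <- random_graph(sample(3:8, 1), 7, 4, p_edge = 0.5)
    ours <- egat_layer_forward(g$node_features, g$edge_index,
                               g$edge_features, p$layers[[1]])$out
    ref <- dense_egat_layer(g$node_features, g$edge_index, g$edge_features,
                            p$layers[[1]], slope = 0.2, concat = TRUE)
    expect_lt(max(abs(ours - ref)), 1e-6)
    # averaged heads (final-layer mode)
    ours_avg <- egat_layer_forward(g$node_features, g$edge_index,
                                   g$edge_features, p$layers[[1]],
                                   concat = FALSE)$out
    ref_avg <- dense_egat_layer(g$node_features, g$edge_index,
                                g$edge_features, p$layers[[1]],
                                slope = 0.2, concat = FALSE)
    expect_lt(max(abs(ours_avg - ref_avg)), 1e-6)
  }
})

test_that("global mean pooling averages per graph", {
  v <- c(1.5, -2, 0.25)
  X <- matrix(rep(v, each = 4), 4, 3)
  expect_equal(as.numeric(global_mean_pool(X, rep(1, 4))), v)
  # permutation within a graph
  set.seed(4)
  X2 <- matrix(rnorm(15), 5, 3)
  expect_equal(global_mean_pool(X2, rep(1, 5)),
               global_mean_pool(X2[sample(5), ], rep(1, 5)))
  # two-graph batch equals per-graph evaluation
  gid <- c(1, 1, 2, 2, 2)
  both <- global_mean_pool(X2, gid)
  expect_equal(both[1, ], colMeans(X2[1:2, ]), tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(both[2, ], colMeans(X2[3:5, ]), tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_error(global_mean_pool(X2, c(1, 1, 2, 2)), "membership")
})

test_that("model forward is deterministic and permutation invariant", {
  set.seed(5)
  sc <- feature_scheme()
  graphs <- tiny_dataset()$graphs[1:12]
  cfg <- egat_config(hidden_dim = 16, n_heads = 4, head_dims = c(8, 6, 5))
  p <- init_egat_params(cfg, ncol(graphs[[1]]$node_features),
                        ncol(graphs[[1]]$edge_features))
  f1 <- model_forward(graphs, p)
  f2 <- model_forward(graphs, p)
  expect_identical(f1$predictions, f2$predictions)
  for (g in graphs[1:6]) {
    perm <- sample(g$n_nodes)
    gp <- permute_graph(g, perm)
    fp <- model_forward(list(gp), p)
    fo <- model_forward(list(g), p)
    expect_lt(max(abs(fp$predictions - fo$predictions)), 1e-6)
    expect_lt(max(abs(fp$embeddings - fo$embeddings)), 1e-6)
  }
})

test_that("shape mismatches raise informative errors", {
  cfg <- egat_config(hidden_dim = 8, n_heads = 2, head_dims = c(6, 6, 5))
  p <- init_egat_params(cfg, 10, 4)
  expect_error(egat_layer_forward(matrix(0, 3, 9), matrix(integer(0), 0, 2),
                                  matrix(0, 0, 4), p$layers[[1]]),
               "does not match W")
  g <- random_graph(4, 10, 3)
  expect_error(egat_layer_forward(g$node_features, g$edge_index,
                                  g$edge_features, p$layers[[1]]),
               "does not match We")
  expect_error(model_forward(list(random_graph(4, 9, 4)), p),
               "does not match the model")
  expect_error(egat_config(hidden_dim = 10, n_heads = 4))
  expect_error(egat_config(head_dims = c(16, 8, 3)), "5 outputs")
})

test_that("parameter count formula matches instantiated models", {
  for (cfg in list(egat_config(hidden_dim = 16, n_heads = 2,
                               head_dims = c(8, 6, 5)),
                   egat_config(hidden_dim = 32, n_heads = 4,
                               head_dims = c(16, 8, 5)))) {
    p <- init_egat_params(cfg, 32, 6)
    expect_equal(count_parameters(cfg, 32, 6), length(params_flatten(p)))
  }
  # doubling hidden_dim changes the count by the closed form: recompute the
  # per-layer shape sums independently for both widths
  by_hand <- function(hd, f_n = 32, f_e = 6, heads = 2,
                      head_dims = c(8, 6, 5)) {
    d <- hd / heads
    n <- (f_n * d + f_e * d + 3 * d) * heads +          # layer 1
      (hd * d + f_e * d + 3 * d) * heads +              # layer 2
      (hd * hd + f_e * hd + 3 * hd) * heads             # final (full width)
    dims <- c(hd, head_dims)
    n + sum(dims[-length(dims)] * dims[-1] + dims[-1])
  }
  c1 <- count_parameters(egat_config(hidden_dim = 16, n_heads = 2,
                                     head_dims = c(8, 6, 5)), 32, 6)
  c2 <- count_parameters(egat_config(hidden_dim = 32, n_heads = 2,
                                     head_dims = c(8, 6, 5)), 32, 6)
  expect_equal(c1, by_hand(16))
  expect_equal(c2 - c1, by_hand(32) - by_hand(16))
})

test_that("analytic gradients match central differences away from roundoff", {
  set.seed(6)
  graphs <- lapply(1:4, function(i) random_graph(sample(3:6, 1), 8, 4,
                                                 id = paste0("g", i)))
  batch <- batch_graphs(graphs)
  cfg <- egat_config(hidden_dim = 8, n_heads = 2, head_dims = c(6, 6, 5))
  p <- init_egat_params(cfg, 8, 4)
  Y <- matrix(rnorm(4 * 5), 4, 5)
  lg <- egat_loss_grad(batch, p, Y)
  gvec <- grads_flatten(lg$grads)
  vec <- params_flatten(p)
  idx <- sample(length(vec), 25)
  eps <- 1e-5
  for (i in idx) {
    v1 <- vec; v1[i] <- v1[i] + eps
    v2 <- vec; v2[i] <- v2[i] - eps
    fd <- (egat_loss_grad(batch, params_unflatten(p, v1), Y)$loss -
             egat_loss_grad(batch, params_unflatten(p, v2), Y)$loss) / (2 * eps)
    rel <- abs(fd - gvec[i]) / max(1e-6, abs(fd) + abs(gvec[i]))
    expect_lt(rel, 1e-4)
  }
})
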