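# Splitting, standardization, training loop, metrics.

test_that("splits are disjoint, exact and deterministic", {
  sp <- split_dataset(100, split_spec(60, 20, 20, seed = 3))
  expect_equal(lengths(sp), c(train = 60L, val = 20L, test = 20L))
  expect_equal(sort(unname(unlist(sp))), 1:100)
  sp2 <- split_dataset(100, split_spec(60, 20, 20, seed = 3))
  expect_identical(sp, sp2)
  expect_error(split_dataset(50, split_spec(40, 10, 10, seed = 1)),
               "exceed")
})

test_that("different seeds overlap at about the hypergeometric rate", {
  a <- split_dataset(100, split_spec(60, 20, 20, seed = 3))$train
  b <- split_dataset(100, split_spec(60, 20, 20, seed = 4))$train
  expect_false(identical(a, b))
  # E[|overlap|]/60 = 60/100 = 0.6
  expect_lt(abs(length(intersect(a, b)) / 60 - 0.6), 0.15)
})

test_that("target standardization round-trips and rejects constants", {
  set.seed(7)
  Y <- cbind(a = rnorm(50, 5, 2), b = runif(50), c = rnorm(50, -3, 0.5))
  std <- standardize_targets(Y)
  Z <- std$transform(Y)
  expect_equal(unname(colMeans(Z)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(std$inverse(Z), Y, tolerance = 1e-12, ignore_attr = TRUE)
  Yc <- cbind(Y, d = rep(2, 50))
  expect_error(standardize_targets(Yc), "zero-variance.*d")
})

test_that("metric identities hold on constructed predictions", {
  d <- tiny_dataset()
  Y <- as.matrix(d$labels[1:40, PROPERTY_NAMES])
  rownames(Y) <- d$labels$mol_id[1:40]
  # predictions identical to labels
  met <- evaluate(Y, d$graphs[1:40], d$labels)
  expect_equal(met$MAE, rep(0, 5))
  expect_equal(met$RMSE, rep(0, 5))
  expect_equal(met$R2, rep(1, 5))
  # constant offset
  met2 <- evaluate(Y + 0.5, d$graphs[1:40], d$labels)
  expect_equal(met2$MAE, rep(0.5, 5), tolerance = 1e-12)
  expect_equal(met2$RMSE, rep(0.5, 5), tolerance = 1e-12)
  # mean predictor has R2 = 0
  Ybar <- matrix(colMeans(Y), 40, 5, byrow = TRUE,
                 dimnames = dimnames(Y))
  met3 <- evaluate(Ybar, d$graphs[1:40], d$labels)
  expect_equal(met3$R2, rep(0, 5), tolerance = 1e-12)
  # RMSE >= MAE always
  set.seed(8)
  met4 <- evaluate(Y + matrix(rnorm(200), 40, 5), d$graphs[1:40], d$labels)
  expect_true(all(met4$RMSE >= met4$MAE))
  expect_true(all(met4$R2 <= 1))
})

test_that("training reduces the loss and is reproducible", {
  d <- tiny_dataset()
  sp <- split_dataset(nrow(d$records), split_spec(100, 25, 25, seed = 5))
  cfg <- train_config(max_epochs = 8, seed = 6)
  ecfg <- egat_config(hidden_dim = 32, n_heads = 4, seed = 6)
  m1 <- train_model(d$graphs, d$labels, sp, cfg, ecfg)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  m2 <- train_model(d$graphs, d$labels, sp, cfg, ecfg)
  expect_identical(m1$history, m2$history)
  expect_equal(params_flatten(m1$params), params_flatten(m2$params))

  # predictions come back in original units with sane magnitudes
  pred <- predict(m1, d$graphs[sp$test])
  expect_equal(colnames(pred), PROPERTY_NAMES)
  expect_true(all(is.finite(pred)))
})

test_that("randomly shuffled labels give near-zero test R2", {
  d <- tiny_dataset()
  sp <- split_dataset(nrow(d$records), split_spec(100, 25, 25, seed = 5))
  shuffled <- d$labels
  set.seed(99)
  perm <- sample(nrow(shuffled))
  shuffled[, PROPERTY_NAMES] <- shuffled[perm, PROPERTY_NAMES]
  m <- train_model(d$graphs, shuffled, sp,
                   train_config(max_epochs = 8, seed = 6),
                   egat_config(hidden_dim = 32, n_heads = 4, seed = 6))
  met <- evaluate(m, d$graphs[sp$test], shuffled)
  expect_true(all(abs(met$R2) < 0.2))
})

test_that("ring-stratified metrics conserve group sizes", {
  d <- tiny_dataset()
  sp <- split_dataset(nrow(d$records), split_spec(100, 25, 25, seed = 5))
  m <- train_model(d$graphs, d$labels, sp,
                   train_config(max_epochs = 4, seed = 6),
                   egat_config(hidden_dim = 16, n_heads = 4, seed = 6))
  rc <- d$records$ring_count[sp$test]
  met <- suppressWarnings(   # sparse ring-count groups warn by design
    metrics_by_ring_count(m, d$graphs[sp$test], d$labels, rc))
  per_group <- unique(met[, c("ring_count", "n")])
  expect_equal(sum(per_group$n), sum(table(rc)[table(rc) >= 2]))
  # single-class evaluation yields a single group
  sel <- which(rc == 2)
  met2 <- metrics_by_ring_count(m, d$graphs[sp$test][sel],
                                d$labels, rep(2L, length(sel)))
  expect_equal(unique(met2$ring_count), 2L)
})

test_that("top_k_errors ranks by absolute error with id tie-breaks", {
  d <- tiny_dataset()
  graphs <- d$graphs[1:20]
  Y <- as.matrix(d$labels[1:20, PROPERTY_NAMES])
  rownames(Y) <- d$labels$mol_id[1:20]

  sp <- split_dataset(nrow(d$records), split_spec(60, 20, 20, seed = 5))
  m <- train_model(d$graphs, d$labels, sp,
                   train_config(max_epochs = 2, seed = 6),
                   egat_config(hidden_dim = 16, n_heads = 2,
                               head_dims = c(8, 6, 5), seed = 6))
  te <- top_k_errors(m, graphs, d$labels, "gap_eV", k = 20)
  expect_equal(nrow(te), 20)
  expect_equal(sort(te$mol_id), sort(d$labels$mol_id[1:20]))
  expect_true(all(diff(te$abs_error) <= 1e-12))

  # a corrupted label dominates the ranking
  labs2 <- d$labels
  labs2$gap_eV[7] <- labs2$gap_eV[7] + 10
  te2 <- top_k_errors(m, graphs, labs2, "gap_eV", k = 5)
  expect_equal(te2$mol_id[1], d$labels$mol_id[7])

  # perfect predictions: all errors zero, ranking falls back to id order
  labs3 <- d$labels
  pred <- predict(m, graphs)
  labs3$gap_eV[1:20] <- pred[, "gap_eV"]
  te3 <- top_k_errors(m, graphs, labs3, "gap_eV", k = 20)
  expect_equal(te3$abs_error, rep(0, 20))
  expect_equal(te3$mol_id, sort(d$labels$mol_id[1:20]))
})

test_that("learning_curve builds nested subsets and one row per size", {
  d <- tiny_dataset()
  sp <- split_dataset(nrow(d$records), split_spec(90, 30, 30, seed = 5))
  lc <- learning_curve(c(30, 90), d$graphs, d$labels, pool = sp$train,
                       val = sp$val, test = sp$test,
                       config = train_config(max_epochs = 3, seed = 6),
                       egat = egat_config(hidden_dim = 16, n_heads = 2,
                                          head_dims = c(8, 6, 5), seed = 6))
  expect_equal(lc$size, c(30, 90))
  expect_equal(ncol(lc), 6)
  expect_error(learning_curve(c(30, 200), d$graphs, d$labels,
                              pool = sp$train, val = sp$val, test = sp$test))
})
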