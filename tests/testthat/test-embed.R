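# PCA, exemplars, fingerprints, similarity, histograms.

test_that("PCA of collinear points loads everything on PC1", {
  t <- seq(-2, 2, length.out = 20)
  X <- cbind(1 + 2 * t, -t, 0.5 * t)
  pca <- pca_fit(X, k = 2)
  expect_equal(pca$explained_variance_ratio[1], 1, tolerance = 1e-12)
  expect_equal(pca$explained_variance_ratio[2], 0, tolerance = 1e-12)
})

test_that("variance ratios sum to one at full rank and components are orthonormal", {
  set.seed(1)
  X <- matrix(rnorm(50 * 8), 50, 8)
  pca <- pca_fit(X, k = 8)
  expect_equal(sum(pca$explained_variance_ratio), 1, tolerance = 1e-10)
  expect_true(all(diff(pca$explained_variance_ratio) <= 1e-12))
  G <- pca$components %*% t(pca$components)
  expect_lt(max(abs(G - diag(8))), 1e-8)
})

test_that("PCA matches a dense covariance eigendecomposition oracle", {
  set.seed(2)
  X <- matrix(rnorm(100 * 20), 100, 20) %*% diag(seq(3, 0.2, length.out = 20))
  k <- 6
  pca <- pca_fit(X, k = k)
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  evr <- eg$values / sum(eg$values)
  expect_equal(pca$explained_variance_ratio, evr[1:k], tolerance = 1e-8)
  # absolute projections agree (signs are convention-dependent)
  Xc <- sweep(X, 2, colMeans(X))
  ref_coords <- Xc %*% eg$vectors[, 1:k]
  expect_lt(max(abs(abs(pca$coords) - abs(ref_coords))), 1e-8)
  # Eckart-Young: reconstruction error equals the discarded variance
  recon <- sweep(pca$coords %*% pca$components, 2, pca$mean, "+")
  err <- sum((X - recon)^2) / (nrow(X) - 1)
  expect_equal(err, sum(eg$values[(k + 1):20]), tolerance = 1e-8)
  # sign convention: largest-|loading| entry positive, deterministic
  for (j in 1:k) {
    expect_gt(pca$components[j, which.max(abs(pca$components[j, ]))], 0)
  }
  expect_error(pca_fit(X, k = 21), "exceeds")
})

test_that("property gradients recover planted axis alignments", {
  set.seed(3)
  X <- matrix(rnorm(80 * 5), 80, 5) %*% diag(c(4, 2, 1, 0.5, 0.25))
  pca <- pca_fit(X, k = 3)
  g1 <- property_gradient(pca$coords, pca$coords[, 1])
  expect_equal(unname(g1[1]), 1, tolerance = 1e-10)
  g2 <- property_gradient(pca$coords, -pca$coords[, 2])
  expect_equal(unname(g2[2]), -1, tolerance = 1e-10)
  # independent property: small correlations under a fixed-seed null
  g3 <- property_gradient(pca$coords, rnorm(80))
  expect_true(all(abs(g3) < 0.35))
  expect_error(property_gradient(pca$coords, rep(1, 80)), "zero variance")
})

test_that("exemplar selection with deterministic tie-breaks", {
  ex <- select_exemplars(c("a", "b", "c"), c(1, 2, 3))
  expect_equal(ex, list(highest = "c", lowest = "a", closest_to_mean = "b"))
  ex2 <- select_exemplars(c("b", "a", "c"), c(5, 5, 5))
  expect_equal(ex2, list(highest = "a", lowest = "a", closest_to_mean = "a"))
  # equal distance to the mean: tie broken by id
  ex3 <- select_exemplars(c("x", "y"), c(0, 10))
  expect_equal(ex3$closest_to_mean, "x")
  # invariance to input ordering
  ids <- c("m3", "m1", "m2"); vals <- c(2, 9, 4)
  ord <- c(2, 3, 1)
  expect_equal(select_exemplars(ids, vals),
               select_exemplars(ids[ord], vals[ord]))
})

test_that("fingerprints are canonical and discriminate structures", {
  f1 <- morgan_fingerprint("c1ccccc1")
  f2 <- morgan_fingerprint("C1=CC=CC=C1")
  expect_identical(f1, f2)
  f3 <- morgan_fingerprint("C1CCCCC1")
  expect_false(identical(f1$bits, f3$bits))
  expect_equal(tanimoto(f1, f2), 1)
  # radius 0 of benzene: all six aromatic CH atoms share one environment
  f0 <- morgan_fingerprint("c1ccccc1", radius = 0)
  expect_equal(length(f0$bits), 1)
})

test_that("tanimoto set arithmetic, symmetry and bounds", {
  a <- make_fp(c(1, 2, 3)); b <- make_fp(c(2, 3, 4))
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(make_fp(1:3), make_fp(7:9)), 0)
  expect_equal(tanimoto(make_fp(integer(0)), make_fp(integer(0))), 1)
  expect_error(tanimoto(a, make_fp(1:3, n_bits = 1024L)), "mismatch")
  set.seed(4)
  for (i in 1:20) {
    x <- make_fp(sample(0:63, sample(0:20, 1)), 64L)
    y <- make_fp(sample(0:63, sample(0:20, 1)), 64L)
    expect_equal(tanimoto(x, y), tanimoto(y, x))
    expect_gte(tanimoto(x, y), 0)
    expect_lte(tanimoto(x, y), 1)
    expect_equal(tanimoto(x, y) == 1, setequal(x$bits, y$bits))
  }
})

test_that("max similarity excludes self and finds duplicates", {
  refs <- data.frame(
    mol_id = c("r1", "r2", "r3"),
    smiles = c("c1ccccc1", "C1CCCCC1", "c1ccncc1"),
    stringsAsFactors = FALSE)
  # same molecule under a different id -> 1.0
  ms <- max_similarity_to_set("q", "c1ccccc1", refs)
  expect_equal(ms$best_value, 1)
  expect_equal(ms$best_id, "r1")
  # self-match excluded by id
  ms2 <- max_similarity_to_set("r1", "c1ccccc1", refs)
  expect_lt(ms2$best_value, 1)
  # a single reference with a disjoint fingerprint scores 0
  refs3 <- data.frame(mol_id = "z", smiles = "S1SSSS1")
  ms3 <- max_similarity_to_set("q", "C1CCCCC1", refs3)
  expect_equal(ms3$best_value, 0)
})

test_that("property histograms conserve counts and report true extremes", {
  d <- tiny_dataset()
  h <- property_histograms(d$labels, bins = 12)
  for (cl in names(h)) {
    expect_equal(sum(h[[cl]]$counts), h[[cl]]$n)
    expect_equal(h[[cl]]$min, min(d$labels[[cl]]))
    expect_equal(h[[cl]]$max, max(d$labels[[cl]]))
  }
  one <- property_histograms(data.frame(gap_eV = 5.4), bins = 10)
  expect_equal(sum(one$gap_eV$counts), 1)
})

test_that("embedding CSV round trip", {
  emb <- structure(list(mol_ids = c("a", "b", "c"),
                        X = matrix(rnorm(12), 3, 4)),
                   class = "embedding_matrix")
  path <- tempfile(fileext = ".csv")
  write_embeddings(emb, path)
  back <- read_embeddings(path)
  expect_equal(back$mol_ids, emb$mol_ids)
  expect_equal(unname(back$X), unname(emb$X), tolerance = 1e-6)
})
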