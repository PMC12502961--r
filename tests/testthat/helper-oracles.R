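# Shared fixtures and independent oracles.

# Independent dense implementation of the edge-aware attention layer: it
# materializes the full N x N score matrix with -Inf masking and loops over
# nodes and heads explicitly. Kept deliberately naive and separate from the
# package kernels.
dense_egat_layer <- function(X, edge_index, edge_features, lp,
                             slope = 0.2, concat = TRUE) {
  N <- nrow(X)
  H <- ncol(lp$a_dst); D <- nrow(lp$a_dst)
  heads_out <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- ((h - 1) * D + 1):(h * D)
    W <- lp$W[, cols, drop = FALSE]
    We <- lp$We[, cols, drop = FALSE]
    Z <- X %*% W
    S <- matrix(-Inf, N, N)   # S[i, j] = score of edge j -> i
    for (i in seq_len(N)) {   # self-loop, zero edge feature
      raw <- sum(lp$a_dst[, h] * Z[i, ]) + sum(lp$a_src[, h] * Z[i, ])
      S[i, i] <- ifelse(raw > 0, raw, slope * raw)
    }
    if (nrow(edge_index) > 0) {
      for (e in seq_len(nrow(edge_index))) {
        j <- edge_index[e, 1]; i <- edge_index[e, 2]
        ze <- as.numeric(edge_features[e, , drop = FALSE] %*% We)
        raw <- sum(lp$a_dst[, h] * Z[i, ]) + sum(lp$a_src[, h] * Z[j, ]) +
          sum(lp$a_e[, h] * ze)
        S[i, j] <- ifelse(raw > 0, raw, slope * raw)
      }
    }
    A <- matrix(0, N, N)
    for (i in seq_len(N)) {
      row <- S[i, ]
      m <- max(row[is.finite(row)])
      ex <- ifelse(is.finite(row), exp(row - m), 0)
      A[i, ] <- ex / sum(ex)
    }
    heads_out[[h]] <- A %*% Z
  }
  pre <- if (concat) do.call(cbind, heads_out)
         else Reduce(`+`, heads_out) / H
  ifelse(pre > 0, pre, exp(pmin(pre, 0)) - 1)   # ELU
}

# random attributed graph (undirected bonds stored as two directed edges
# with shared features), in the molecular_graph layout
random_graph <- function(n_nodes, f_n, f_e, p_edge = 0.5, id = "g") {
  n_nodes <- as.integer(n_nodes)
  X <- matrix(stats::rnorm(n_nodes * f_n), n_nodes, f_n)
  src <- integer(0); dst <- integer(0); EF <- NULL
  if (n_nodes >= 2) {
    for (a in seq_len(n_nodes - 1)) {
      for (b in (a + 1):n_nodes) {
        if (stats::runif(1) < p_edge) {
          feat <- stats::rnorm(f_e)
          src <- c(src, a, b); dst <- c(dst, b, a)
          EF <- rbind(EF, feat, feat)
        }
      }
    }
  }
  if (is.null(EF)) EF <- matrix(0, 0, f_e)
  structure(list(mol_id = id, node_features = X,
                 edge_index = cbind(src, dst), edge_features = EF,
                 n_nodes = n_nodes),
            class = "molecular_graph")
}

# relabel the nodes of a molecular_graph by a permutation
permute_graph <- function(g, perm) {
  inv <- order(perm)   # node i moves to position perm[i]
  ei <- g$edge_index
  if (nrow(ei) > 0) ei <- cbind(perm[ei[, 1]], perm[ei[, 2]])
  structure(list(mol_id = g$mol_id,
                 node_features = g$node_features[inv, , drop = FALSE],
                 edge_index = ei,
                 edge_features = g$edge_features,
                 n_nodes = g$n_nodes),
            class = "molecular_graph")
}

# small labeled dataset shared by training-related unit tests (memoized)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      recs <- generate_molecules(generator_config(seed = 101, n_molecules = 150))
      labs <- label_molecules(recs, huckel_params(noise_sd = 0), seed = 102)
      graphs <- featurize_dataset(recs, feature_scheme())
      cache <<- list(records = recs, labels = labs, graphs = graphs)
    }
    cache
  }
})

make_fp <- function(bits, n_bits = 2048L) {
  structure(list(bits = as.integer(sort(unique(bits))),
                 n_bits = as.integer(n_bits), radius = 3L),
            class = "fingerprint")
}
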