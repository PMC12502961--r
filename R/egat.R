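# Edge-aware graph attention regressor.
#
# Three message-passing layers score each directed edge j -> i (plus an
# implicit self-loop with a zero edge-feature vector) as
#   s_ij = leakyReLU( a_dst . W h_i + a_src . W h_j + a_e . W_e e_ij ),
# normalize the scores over the incoming edges of i by a max-shifted
# softmax, and update h_i as ELU of the attention-weighted sum of the
# transformed source features. Hidden layers concatenate heads; the final
# message layer averages them. Global mean pooling then yields the
# molecular embedding, which three fully connected layers map to the five
# properties. Gradients are computed by hand (reverse accumulation over the
# cached forward pass); all heavy operations are matrix products and
# `rowsum()` segment reductions, so batches of graphs are processed as one
# block-diagonal graph.

#' Model configuration
#'
#' @param n_message_layers Number of attention layers (default 3).
#' @param hidden_dim Node representation width after head concatenation;
#'   must be divisible by `n_heads`.
#' @param n_heads Attention heads (concatenated in hidden layers, averaged
#'   in the final message layer).
#' @param head_dims Widths of the three fully connected output layers; the
#'   last must be 5 (gap, IP, EA, E_ox, E_red).
#' @param attn_slope Negative slope of the leaky rectifier in the attention
#'   scores.
#' @param dropout_rate Feature dropout applied before each message layer
#'   during training (0 disables it; evaluation never drops).
#' @param seed Seed of the Glorot parameter initialization.
#' @return A list of class `egat_config`.
#' @export
egat_config <- function(n_message_layers = 3L, hidden_dim = 128L,
                        n_heads = 4L, head_dims = c(64L, 32L, 5L),
                        attn_slope = 0.2, dropout_rate = 0, seed = 1L) {
  stopifnot(n_message_layers >= 1L, hidden_dim %% n_heads == 0L,
            length(head_dims) >= 1L,
            dropout_rate >= 0, dropout_rate < 1)
  if (utils::tail(head_dims, 1L) != 5L) {
    stop("the final fully connected layer must have 5 outputs")
  }
  structure(list(n_message_layers = as.integer(n_message_layers),
                 hidden_dim = as.integer(hidden_dim),
                 n_heads = as.integer(n_heads),
                 head_dims = as.integer(head_dims),
                 attn_slope = attn_slope,
                 dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "egat_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# per-layer shapes implied by a config and feature dims
egat_layer_shapes <- function(config, f_n) {
  L <- config$n_message_layers
  H <- config$n_heads
  lapply(seq_len(L), function(l) {
    list(d_in = if (l == 1L) f_n else config$hidden_dim,
         d_out = if (l == L) config$hidden_dim else config$hidden_dim / H,
         heads = H,
         concat = l < L)
  })
}

#' Initialize model parameters
#'
#' Uniform Glorot initialization, deterministic given `config$seed`.
#'
#' @param config An [egat_config()].
#' @param f_n,f_e Node and edge feature dimensions (see [scheme_dims()]).
#' @return A list of class `egat_params` holding per-layer `W`, `We`
#'   (stored with all heads side by side), attention vectors `a_dst`,
#'   `a_src`, `a_e` (columns = heads), and the fully connected stack.
#' @export
init_egat_params <- function(config, f_n, f_e) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  shapes <- egat_layer_shapes(config, f_n)
  layers <- lapply(shapes, function(sh) {
    D <- sh$d_out; H <- sh$heads
    list(W = glorot(sh$d_in, D * H),
         We = glorot(f_e, D * H),
         a_dst = glorot(D, H),
         a_src = glorot(D, H),
         a_e = glorot(D, H))
  })
  dims <- c(config$hidden_dim, config$head_dims)
  fc <- lapply(seq_len(length(dims) - 1L), function(i) {
    list(W = glorot(dims[i], dims[i + 1L]), b = rep(0, dims[i + 1L]))
  })
  structure(list(config = config, f_n = f_n, f_e = f_e,
                 layers = layers, fc = fc),
            class = "egat_params")
}

#' Closed-form parameter count
#'
#' @param config An [egat_config()].
#' @param f_n,f_e Feature dimensions.
#' @return Integer: total number of trainable scalars, matching
#'   [init_egat_params()].
#' @export
count_parameters <- function(config, f_n, f_e) {
  shapes <- egat_layer_shapes(config, f_n)
  n <- 0L
  for (sh in shapes) {
    D <- sh$d_out; H <- sh$heads
    n <- n + sh$d_in * D * H + f_e * D * H + 3L * D * H
  }
  dims <- c(config$hidden_dim, config$head_dims)
  for (i in seq_len(length(dims) - 1L)) {
    n <- n + dims[i] * dims[i + 1L] + dims[i + 1L]
  }
  as.integer(n)
}

# branch-free activations (keep matrix shape, avoid ifelse allocations;
# exp(x * neg) evaluates exp(0) = 1 on the positive side, so no overflow)
elu <- function(x) {
  pos <- x > 0
  neg <- 1 - pos
  x * pos + (exp(x * neg) - 1) * neg
}
elu_grad <- function(x) {
  pos <- x > 0
  neg <- 1 - pos
  pos + exp(x * neg) * neg
}
lrelu <- function(x, slope) {
  pos <- x > 0
  x * (pos + slope * (1 - pos))
}
lrelu_grad <- function(x, slope) {
  pos <- x > 0
  pos + slope * (1 - pos)
}

# Grouping structure of the directed edges (with self-loops appended) of a
# batched graph: `P` holds, per destination node, the padded indices of its
# incoming entries, enabling a vectorized per-group maximum.
edge_structure <- function(src, dst, N) {
  src_all <- c(src, seq_len(N))
  dst_all <- c(dst, seq_len(N))
  cnt <- tabulate(dst_all, N)
  K <- max(cnt)
  ord <- order(dst_all)
  P <- matrix(0L, N, K)
  P[cbind(dst_all[ord], sequence(cnt))] <- ord
  if (K > 1L) {
    for (k in 2:K) {
      miss <- P[, k] == 0L
      P[miss, k] <- P[miss, 1L]
    }
  }
  list(src_all = src_all, dst_all = dst_all, P = P, E = length(src), N = N)
}

group_max <- function(S, st) {
  M <- S[st$P[, 1L], , drop = FALSE]
  K <- ncol(st$P)
  if (K > 1L) for (k in 2:K) M <- pmax(M, S[st$P[, k], , drop = FALSE])
  M
}

# HD x H block matrix with attention vector a (D x H) in block h of column h
attn_block <- function(a) {
  D <- nrow(a); H <- ncol(a)
  Ab <- matrix(0, D * H, H)
  Ab[cbind(seq_len(D * H), rep(seq_len(H), each = D))] <- as.vector(a)
  Ab
}

#' Batch molecular graphs into one block-diagonal graph
#'
#' @param graphs List of `molecular_graph` objects.
#' @return A list with the stacked node matrix `X`, directed edge vectors
#'   `src`/`dst`, stacked `efeat`, per-node `graph_id`, per-graph node
#'   counts, and `B` (number of graphs).
#' @export
batch_graphs <- function(graphs) {
  nn <- vapply(graphs, `[[`, integer(1), "n_nodes")
  if (any(nn == 0L)) stop("graph with zero nodes in batch")
  offs <- cumsum(c(0L, nn[-length(nn)]))
  X <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  src <- integer(0); dst <- integer(0)
  efeat <- do.call(rbind, lapply(graphs, `[[`, "edge_features"))
  for (i in seq_along(graphs)) {
    ei <- graphs[[i]]$edge_index
    if (nrow(ei) > 0L) {
      src <- c(src, ei[, 1L] + offs[i])
      dst <- c(dst, ei[, 2L] + offs[i])
    }
  }
  list(X = X, src = src, dst = dst, efeat = efeat,
       graph_id = rep(seq_along(graphs), nn),
       n_per_graph = nn, B = length(graphs),
       st = edge_structure(src, dst, nrow(X)))
}

# forward through one attention layer on a (batched) graph, returning the
# activation plus everything the backward pass needs; all heads are
# processed at once through block matrices and single rowsum reductions
egat_layer_fwd <- function(X, st, efeat, lp, slope, concat) {
  N <- nrow(X); E <- st$E
  HD <- ncol(lp$W); H <- ncol(lp$a_dst); D <- HD / H
  Z <- X %*% lp$W
  Ze <- if (E > 0L) efeat %*% lp$We else matrix(0, 0L, HD)
  U <- Z %*% attn_block(lp$a_dst)                   # N x H
  V <- Z %*% attn_block(lp$a_src)
  W_edge <- rbind(if (E > 0L) Ze %*% attn_block(lp$a_e)
                  else matrix(0, 0L, H),
                  matrix(0, N, H))                  # zero for self-loops
  sraw <- U[st$dst_all, , drop = FALSE] + V[st$src_all, , drop = FALSE] +
    W_edge
  s <- lrelu(sraw, slope)
  mx <- group_max(s, st)
  ex <- exp(s - mx[st$dst_all, , drop = FALSE])
  denom <- rowsum(ex, st$dst_all)                   # rows ordered 1..N
  alpha <- ex / denom[st$dst_all, , drop = FALSE]
  hsel <- rep(seq_len(H), each = D)
  agg <- rowsum(Z[st$src_all, , drop = FALSE] *
                  alpha[, hsel, drop = FALSE], st$dst_all)
  dimnames(agg) <- NULL
  if (concat) {
    pre <- agg
  } else {
    pre <- agg[, seq_len(D), drop = FALSE]
    if (H > 1L) for (h in 2:H) {
      pre <- pre + agg[, (h - 1L) * D + seq_len(D), drop = FALSE]
    }
    pre <- pre / H
  }
  list(out = elu(pre), pre = pre, Z = Z, Ze = Ze, sraw = sraw,
       alpha = alpha, X = X, st = st, H = H, D = D, concat = concat)
}

# reverse pass of egat_layer_fwd; returns gradients w.r.t. the layer
# parameters and the layer input
egat_layer_bwd <- function(cache, lp, slope, dOut, efeat) {
  st <- cache$st
  H <- cache$H; D <- cache$D; HD <- H * D
  N <- nrow(cache$X); E <- st$E
  hsel <- rep(seq_len(H), each = D)
  dPre <- dOut * elu_grad(cache$pre)
  dAggF <- if (cache$concat) dPre
           else dPre[, rep(seq_len(D), H), drop = FALSE] / H
  dAgg_e <- dAggF[st$dst_all, , drop = FALSE]
  Zs <- cache$Z[st$src_all, , drop = FALSE]
  # d(loss)/d(alpha), per head: block-wise row sums of dAgg_e * Z_src
  blocks <- matrix(0, HD, H)
  blocks[cbind(seq_len(HD), hsel)] <- 1
  dal <- (dAgg_e * Zs) %*% blocks                      # EA x H
  # aggregation term into source-transformed features
  dZ <- rowsum(dAgg_e * cache$alpha[, hsel, drop = FALSE], st$src_all)
  # softmax backward
  tmp <- cache$alpha * dal
  ssum <- rowsum(tmp, st$dst_all)
  ds <- tmp - cache$alpha * ssum[st$dst_all, , drop = FALSE]
  dsraw <- ds * lrelu_grad(cache$sraw, slope)          # EA x H
  du <- rowsum(dsraw, st$dst_all)                      # N x H
  dv <- rowsum(dsraw, st$src_all)
  dZ <- dZ + du %*% t(attn_block(lp$a_dst)) + dv %*% t(attn_block(lp$a_src))
  block_diag <- function(Tm) matrix(Tm[cbind(seq_len(HD), hsel)], D, H)
  g <- list(W = crossprod(cache$X, dZ),
            We = NULL,
            a_dst = block_diag(crossprod(cache$Z, du)),
            a_src = block_diag(crossprod(cache$Z, dv)),
            a_e = matrix(0, D, H))
  if (E > 0L) {
    dw_real <- dsraw[seq_len(E), , drop = FALSE]
    g$a_e <- block_diag(crossprod(cache$Ze, dw_real))
    dZe <- dw_real %*% t(attn_block(lp$a_e))
    g$We <- crossprod(efeat, dZe)
  } else {
    g$We <- matrix(0, nrow(lp$We), ncol(lp$We))
  }
  list(grads = g, dX = dZ %*% t(lp$W))
}

#' Forward pass of a single attention layer
#'
#' Thin public wrapper around the batched layer kernel, mainly for
#' inspection and testing of the attention mechanism itself.
#'
#' @param node_features N x F matrix.
#' @param edge_index E x 2 matrix of directed (src, dst) pairs; may have
#'   zero rows.
#' @param edge_features E x F_e matrix.
#' @param layer_params One element of `egat_params$layers`.
#' @param attn_slope Leaky-rectifier slope.
#' @param concat Concatenate heads (`TRUE`) or average them.
#' @return A list with `out` (updated node features) and `alpha` (attention
#'   weights over directed edges followed by the N self-loops; columns =
#'   heads).
#' @export
egat_layer_forward <- function(node_features, edge_index, edge_features,
                               layer_params, attn_slope = 0.2,
                               concat = TRUE) {
  if (ncol(node_features) != nrow(layer_params$W)) {
    stop("node feature dim ", ncol(node_features), " does not match W (",
         nrow(layer_params$W), " x ", ncol(layer_params$W), ")")
  }
  if (nrow(edge_index) > 0L && ncol(edge_features) != nrow(layer_params$We)) {
    stop("edge feature dim ", ncol(edge_features), " does not match We (",
         nrow(layer_params$We), " x ", ncol(layer_params$We), ")")
  }
  st <- edge_structure(as.integer(edge_index[, 1L]),
                       as.integer(edge_index[, 2L]),
                       nrow(node_features))
  cache <- egat_layer_fwd(node_features, st, edge_features, layer_params,
                          attn_slope, concat)
  list(out = cache$out, alpha = cache$alpha,
       src = st$src_all, dst = st$dst_all)
}

#' Global mean pooling
#'
#' @param node_features N x D matrix.
#' @param graph_membership Integer graph id per node (1..B).
#' @return B x D matrix of per-graph means.
#' @export
global_mean_pool <- function(node_features, graph_membership) {
  if (length(graph_membership) != nrow(node_features)) {
    stop("membership length must equal the number of nodes")
  }
  counts <- as.vector(table(graph_membership))
  if (any(counts == 0L)) stop("graph with zero nodes")
  rowsum(node_features, graph_membership) / counts
}

# full forward with caches (internal); X dropout masks applied when training
egat_forward <- function(batch, params, training = FALSE,
                         dropout_rate = 0) {
  cfg <- params$config
  X <- batch$X
  caches <- vector("list", length(params$layers))
  masks <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    if (training && dropout_rate > 0) {
      mask <- matrix(stats::rbinom(length(X), 1L, 1 - dropout_rate) /
                       (1 - dropout_rate), nrow(X), ncol(X))
      masks[[l]] <- mask
      X <- X * mask
    }
    concat <- l < length(params$layers)
    caches[[l]] <- egat_layer_fwd(X, batch$st, batch$efeat,
                                  params$layers[[l]], cfg$attn_slope, concat)
    X <- caches[[l]]$out
  }
  counts <- batch$n_per_graph
  pooled <- rowsum(X, batch$graph_id) / counts
  dimnames(pooled) <- NULL
  fc_in <- pooled; fc_caches <- list()
  for (i in seq_along(params$fc)) {
    lin <- fc_in %*% params$fc[[i]]$W +
      matrix(params$fc[[i]]$b, nrow(fc_in), length(params$fc[[i]]$b),
             byrow = TRUE)
    act <- if (i < length(params$fc)) elu(lin) else lin
    fc_caches[[i]] <- list(input = fc_in, lin = lin)
    fc_in <- act
  }
  list(pred = fc_in, embedding = pooled, caches = caches, masks = masks,
       fc_caches = fc_caches)
}

# mean-squared-error loss over all outputs plus full gradient
egat_loss_grad <- function(batch, params, Y, training = FALSE,
                           dropout_rate = 0) {
  fwd <- egat_forward(batch, params, training, dropout_rate)
  resid <- fwd$pred - Y
  n_out <- length(resid)
  loss <- sum(resid^2) / n_out
  dA <- 2 * resid / n_out
  gfc <- vector("list", length(params$fc))
  for (i in rev(seq_along(params$fc))) {
    cc <- fwd$fc_caches[[i]]
    dLin <- if (i < length(params$fc)) dA * elu_grad(cc$lin) else dA
    gfc[[i]] <- list(W = crossprod(cc$input, dLin), b = colSums(dLin))
    dA <- dLin %*% t(params$fc[[i]]$W)
  }
  # pooling backward
  dX <- dA[batch$graph_id, , drop = FALSE] / batch$n_per_graph[batch$graph_id]
  glayers <- vector("list", length(params$layers))
  for (l in rev(seq_along(params$layers))) {
    bw <- egat_layer_bwd(fwd$caches[[l]], params$layers[[l]],
                         params$config$attn_slope, dX, batch$efeat)
    glayers[[l]] <- bw$grads
    dX <- bw$dX
    if (training && dropout_rate > 0 && !is.null(fwd$masks[[l]])) {
      dX <- dX * fwd$masks[[l]]
    }
  }
  list(loss = loss, grads = list(layers = glayers, fc = gfc), fwd = fwd)
}

#' Run the model on a batch of graphs
#'
#' Deterministic in evaluation mode (dropout off).
#'
#' @param graphs List of `molecular_graph` objects (or a prebuilt batch
#'   from [batch_graphs()]).
#' @param params An `egat_params` object.
#' @return A list with `predictions` (B x 5, model output space) and
#'   `embeddings` (B x hidden_dim pooled graph vectors).
#' @export
model_forward <- function(graphs, params) {
  batch <- if (is.list(graphs) && !is.null(graphs$graph_id)) graphs
           else batch_graphs(graphs)
  if (ncol(batch$X) != params$f_n) {
    stop("node feature dim ", ncol(batch$X),
         " does not match the model (", params$f_n, ")")
  }
  fwd <- egat_forward(batch, params, training = FALSE)
  list(predictions = fwd$pred, embeddings = fwd$embedding)
}

# ---- parameter vector utilities (optimizer / gradient checks) -------------

params_flatten <- function(p) {
  unlist(lapply(p$layers, function(l) {
    c(l$W, l$We, l$a_dst, l$a_src, l$a_e)
  }), use.names = FALSE) |>
    c(unlist(lapply(p$fc, function(l) c(l$W, l$b)), use.names = FALSE))
}

grads_flatten <- function(g) {
  c(unlist(lapply(g$layers, function(l) {
    c(l$W, l$We, l$a_dst, l$a_src, l$a_e)
  }), use.names = FALSE),
    unlist(lapply(g$fc, function(l) c(l$W, l$b)), use.names = FALSE))
}

params_unflatten <- function(p, vec) {
  pos <- 0L
  take <- function(template) {
    k <- length(template)
    out <- vec[(pos + 1L):(pos + k)]
    pos <<- pos + k
    if (is.matrix(template)) matrix(out, nrow(template), ncol(template))
    else out
  }
  for (l in seq_along(p$layers)) {
    for (nm in c("W", "We", "a_dst", "a_src", "a_e")) {
      p$layers[[l]][[nm]] <- take(p$layers[[l]][[nm]])
    }
  }
  for (i in seq_along(p$fc)) {
    p$fc[[i]]$W <- take(p$fc[[i]]$W)
    p$fc[[i]]$b <- take(p$fc[[i]]$b)
  }
  stopifnot(pos == length(vec))
  p
}
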