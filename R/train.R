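# Multi-task training and evaluation of the attention regressor.
#
# The loss is the mean squared error averaged over the five z-scored
# targets (z-scoring by training-set mean/sd, so all tasks weigh equally);
# optimization is Adam with early stopping on the summed validation loss,
# returning the parameters of the best validation epoch. Metrics are always
# reported in the original units (eV / V).

PROPERTY_NAMES <- c("gap_eV", "ip_eV", "ea_eV", "eox_V", "ered_V")

#' Train/validation/test split specification
#'
#' @param n_train,n_val,n_test Set sizes.
#' @param seed RNG seed of the random draw.
#' @export
split_spec <- function(n_train, n_val, n_test, seed = 1L) {
  stopifnot(n_train >= 1L, n_val >= 0L, n_test >= 0L)
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test), seed = as.integer(seed)),
            class = "split_spec")
}

#' Randomly split a dataset into disjoint train/validation/test sets
#'
#' @param n_records Number of records (or a records data frame).
#' @param spec A [split_spec()].
#' @return A list of integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n_records, spec) {
  if (is.data.frame(n_records)) n_records <- nrow(n_records)
  total <- spec$n_train + spec$n_val + spec$n_test
  if (total > n_records) {
    stop("split sizes (", total, ") exceed dataset size (", n_records, ")")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  idx <- sample.int(n_records, total)
  list(train = sort(idx[seq_len(spec$n_train)]),
       val = sort(idx[spec$n_train + seq_len(spec$n_val)]),
       test = sort(idx[spec$n_train + spec$n_val + seq_len(spec$n_test)]))
}

#' Per-property z-scoring transform fitted on training targets
#'
#' @param train_targets Numeric matrix (rows = molecules, columns =
#'   properties) of training labels.
#' @return A list with `mu`, `sd`, and the functions `transform(x)` and
#'   `inverse(z)`.
#' @export
standardize_targets <- function(train_targets) {
  train_targets <- as.matrix(train_targets)
  if (nrow(train_targets) < 2L) stop("need at least 2 training rows")
  mu <- colMeans(train_targets)
  sd <- apply(train_targets, 2L, stats::sd)
  zero <- which(sd == 0 | !is.finite(sd))
  if (length(zero) > 0L) {
    stop("zero-variance propert",
         if (length(zero) > 1) "ies: " else "y: ",
         paste(colnames(train_targets)[zero], collapse = ", "))
  }
  list(mu = mu, sd = sd,
       transform = function(x) sweep(sweep(as.matrix(x), 2L, mu), 2L, sd, "/"),
       inverse = function(z) sweep(sweep(as.matrix(z), 2L, sd, "*"), 2L, mu, "+"))
}

#' Training hyperparameters
#'
#' The loss is the mean squared error over the five z-scored targets.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Graphs per minibatch.
#' @param max_epochs Upper bound on epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param seed Seed for batch shuffling (and dropout, when enabled).
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64L,
                         max_epochs = 40L, patience = 10L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1L, max_epochs >= 1L,
            patience >= 1L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

# label data frame / matrix -> aligned numeric matrix
label_matrix <- function(labels, mol_ids = NULL) {
  if (is.data.frame(labels) && "mol_id" %in% names(labels)) {
    rows <- if (is.null(mol_ids)) seq_len(nrow(labels))
            else match(mol_ids, labels$mol_id)
    if (anyNA(rows)) stop("labels missing for some molecules")
    m <- as.matrix(labels[rows, PROPERTY_NAMES])
    rownames(m) <- labels$mol_id[rows]
    m
  } else {
    as.matrix(labels)
  }
}

#' Train the attention regressor
#'
#' @param graphs List of `molecular_graph` objects (one per record).
#' @param labels Property data frame (with `mol_id`) or numeric matrix
#'   aligned with `graphs`; all train/val rows must be fully labeled.
#' @param split Index list from [split_dataset()] (uses `train` and `val`).
#' @param config A [train_config()].
#' @param egat An [egat_config()].
#' @return An `egat_model`: fitted parameters, the target transform, and a
#'   per-epoch `history` data frame (`epoch`, `train_loss`, `val_loss`).
#' @export
train_model <- function(graphs, labels, split, config = train_config(),
                        egat = egat_config()) {
  ids <- vapply(graphs, `[[`, character(1), "mol_id")
  Y_all <- label_matrix(labels, ids)
  tr <- split$train; va <- split$val
  if (anyNA(Y_all[c(tr, va), ])) stop("train/validation labels contain NA")
  std <- standardize_targets(Y_all[tr, , drop = FALSE])
  Yz <- std$transform(Y_all)

  f_n <- ncol(graphs[[1L]]$node_features)
  f_e <- ncol(graphs[[1L]]$edge_features)
  params <- init_egat_params(egat, f_n, f_e)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  theta <- params_flatten(params)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0L

  val_batches <- lapply(index_chunks(va, 256L), function(ch) {
    list(ch = ch, b = batch_graphs(graphs[ch]))
  })
  val_loss_fn <- function(pp) {
    tot <- 0; nn <- 0
    for (vb in val_batches) {
      pred <- egat_forward(vb$b, pp)$pred
      tot <- tot + sum((pred - Yz[vb$ch, , drop = FALSE])^2)
      nn <- nn + length(vb$ch) * ncol(Yz)
    }
    tot / nn
  }

  best_val <- Inf; best_theta <- theta; since_best <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample(tr)
    ep_loss <- 0; ep_n <- 0L
    for (ch in index_chunks(perm, config$batch_size)) {
      b <- batch_graphs(graphs[ch])
      lg <- egat_loss_grad(b, params, Yz[ch, , drop = FALSE],
                           training = TRUE,
                           dropout_rate = egat$dropout_rate)
      if (!is.finite(lg$loss)) {
        stop("non-finite training loss at epoch ", epoch,
             " (batch of ", length(ch), " graphs); last finite epoch loss: ",
             if (ep_n > 0) ep_loss / ep_n else NA)
      }
      gvec <- grads_flatten(lg$grads)
      t_step <- t_step + 1L
      m <- b1 * m + (1 - b1) * gvec
      v <- b2 * v + (1 - b2) * gvec^2
      mhat <- m / (1 - b1^t_step)
      vhat <- v / (1 - b2^t_step)
      theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + eps)
      params <- params_unflatten(params, theta)
      ep_loss <- ep_loss + lg$loss * length(ch)
      ep_n <- ep_n + length(ch)
    }
    vl <- if (length(va) > 0L) val_loss_fn(params) else ep_loss / ep_n
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / ep_n,
                                         val_loss = vl))
    if (vl < best_val - 1e-9) {
      best_val <- vl; best_theta <- theta; since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  params <- params_unflatten(params, best_theta)
  structure(list(params = params, egat_config = egat,
                 train_config = config,
                 target_mu = std$mu, target_sd = std$sd,
                 property_names = colnames(Y_all),
                 history = history, best_val_loss = best_val,
                 version = "egat-checkpoint-v1"),
            class = "egat_model")
}

index_chunks <- function(idx, size) {
  if (length(idx) == 0L) return(list())
  split(idx, ceiling(seq_along(idx) / size))
}

#' Predict properties for molecular graphs
#'
#' @param object An `egat_model`.
#' @param graphs List of `molecular_graph` objects.
#' @param ... Unused.
#' @return Numeric matrix (graphs x 5) of predictions in original units,
#'   with the pooled embeddings attached as attribute `"embeddings"`.
#' @export
predict.egat_model <- function(object, graphs, ...) {
  preds <- NULL; embs <- NULL
  for (ch in index_chunks(seq_along(graphs), 256L)) {
    fw <- model_forward(graphs[ch], object$params)
    preds <- rbind(preds, fw$predictions)
    embs <- rbind(embs, fw$embeddings)
  }
  out <- sweep(sweep(preds, 2L, object$target_sd, "*"), 2L,
               object$target_mu, "+")
  colnames(out) <- object$property_names
  rownames(out) <- vapply(graphs, `[[`, character(1), "mol_id")
  attr(out, "embeddings") <- embs
  out
}

#' Pooled molecular embeddings from a fitted model
#'
#' @param model An `egat_model`.
#' @param graphs List of `molecular_graph` objects.
#' @return An `embedding_matrix`: list with `mol_ids` and the M x D matrix
#'   `X`.
#' @export
model_embeddings <- function(model, graphs) {
  pred <- predict(model, graphs)
  structure(list(mol_ids = rownames(pred), X = attr(pred, "embeddings")),
            class = "embedding_matrix")
}

metric_row <- function(y, yhat) {
  resid <- yhat - y
  ss_tot <- sum((y - mean(y))^2)
  c(MAE = mean(abs(resid)), RMSE = sqrt(mean(resid^2)),
    R2 = 1 - sum(resid^2) / ss_tot)
}

#' Evaluate predictions against labels
#'
#' @param model An `egat_model` (or a precomputed prediction matrix).
#' @param graphs Graphs of the evaluation set.
#' @param labels Property data frame or matrix for the same molecules.
#' @return A `metrics_table` data frame: one row per property with `MAE`,
#'   `RMSE` and `R2` (coefficient of determination against the
#'   evaluation-set mean), in original units.
#' @export
evaluate <- function(model, graphs, labels) {
  if (length(graphs) == 0L) stop("empty evaluation set")
  pred <- if (is.matrix(model)) model else predict(model, graphs)
  Y <- label_matrix(labels, rownames(pred))
  rows <- t(vapply(seq_len(ncol(Y)), function(j) metric_row(Y[, j], pred[, j]),
                   numeric(3)))
  out <- data.frame(property = colnames(Y), rows, row.names = NULL)
  class(out) <- c("metrics_table", "data.frame")
  out
}

#' Metrics stratified by ring count
#'
#' @param model An `egat_model`.
#' @param graphs Evaluation graphs.
#' @param labels Evaluation labels.
#' @param ring_counts Integer ring count per graph.
#' @return A `metrics_table` with one row per (ring_count, property) group
#'   plus the group size `n`. Empty groups are omitted.
#' @export
metrics_by_ring_count <- function(model, graphs, labels, ring_counts) {
  stopifnot(length(ring_counts) == length(graphs))
  pred <- predict(model, graphs)
  Y <- label_matrix(labels, rownames(pred))
  out <- NULL
  for (rc in sort(unique(ring_counts))) {
    sel <- which(ring_counts == rc)
    if (length(sel) < 2L) {
      warning("ring-count group ", rc, " has fewer than 2 molecules; omitted")
      next
    }
    rows <- t(vapply(seq_len(ncol(Y)),
                     function(j) metric_row(Y[sel, j], pred[sel, j]),
                     numeric(3)))
    out <- rbind(out, data.frame(ring_count = rc, property = colnames(Y),
                                 rows, n = length(sel), row.names = NULL))
  }
  class(out) <- c("metrics_table", "data.frame")
  out
}

#' Learning curve over nested training subsets
#'
#' Smaller training sets are prefixes of a single seeded permutation of the
#' training pool, so they are nested by construction. One model is trained
#' per size with identical seeds and configs; test MAE per property is
#' reported.
#'
#' @param sizes Ascending training-set sizes.
#' @param graphs All graphs.
#' @param labels All labels.
#' @param pool Training-pool indices.
#' @param val,test Validation / test indices (fixed across sizes).
#' @param config A [train_config()].
#' @param egat An [egat_config()].
#' @return Data frame: `size` plus one MAE column per property.
#' @export
learning_curve <- function(sizes, graphs, labels, pool, val, test,
                           config = train_config(), egat = egat_config()) {
  stopifnot(!is.unsorted(sizes), max(sizes) <= length(pool))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  perm <- local({
    set.seed(config$seed)
    sample(pool)
  })
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  out <- NULL
  for (s in sizes) {
    model <- train_model(graphs, labels,
                         list(train = perm[seq_len(s)], val = val),
                         config, egat)
    met <- evaluate(model, graphs[test], labels)
    row <- stats::setNames(as.list(met$MAE), paste0("mae_", met$property))
    out <- rbind(out, data.frame(size = s, row))
  }
  out
}

#' Molecules with the largest absolute prediction errors
#'
#' @param model An `egat_model`.
#' @param graphs Evaluation graphs.
#' @param labels Evaluation labels.
#' @param property One of the five property names.
#' @param k Number of molecules to return.
#' @return Data frame ranked by descending absolute error (ties broken by
#'   `mol_id`): `mol_id`, `actual`, `predicted`, `abs_error`.
#' @export
top_k_errors <- function(model, graphs, labels, property = "gap_eV",
                         k = 10L) {
  stopifnot(k <= length(graphs), property %in% PROPERTY_NAMES)
  pred <- predict(model, graphs)
  Y <- label_matrix(labels, rownames(pred))
  err <- abs(pred[, property] - Y[, property])
  ord <- order(-err, rownames(pred))
  sel <- ord[seq_len(k)]
  data.frame(mol_id = rownames(pred)[sel],
             actual = Y[sel, property],
             predicted = pred[sel, property],
             abs_error = err[sel],
             row.names = NULL)
}
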