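# Model checkpoints: a versioned container with the architecture config,
# feature-scheme version, target transform and all parameter arrays.

#' Save / load a fitted model
#'
#' @param model An `egat_model` from [train_model()].
#' @param path Destination file (RDS).
#' @param scheme The [feature_scheme()] the model was trained with; stored
#'   so inference can rebuild identical graphs.
#' @export
save_model <- function(model, path, scheme = feature_scheme()) {
  stopifnot(inherits(model, "egat_model"))
  obj <- list(version = model$version, model = model, scheme = scheme)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns a list with `model` and `scheme`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, "egat-checkpoint-v1")) {
    stop("unsupported checkpoint version: ", obj$version)
  }
  obj[c("model", "scheme")]
}
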