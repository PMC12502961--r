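# Embedding-space and chemical-similarity analysis: PCA of pooled model
# embeddings with property gradients and exemplar molecules, property
# histograms, and circular-fingerprint novelty analysis for high-error
# molecules.

#' Principal component analysis of an embedding matrix
#'
#' Mean-centering followed by singular value decomposition. Component signs
#' follow a deterministic convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param X M x D numeric matrix (rows = molecules).
#' @param k Number of components, at most `min(M, D)`.
#' @return A list of class `pca_result`: `mean` (D), `components` (k x D,
#'   orthonormal rows), `explained_variance_ratio` (k, non-increasing,
#'   sums to at most 1), `coords` (M x k projections).
#' @export
pca_fit <- function(X, k = 2L) {
  X <- as.matrix(X)
  M <- nrow(X); D <- ncol(X)
  if (M < 2L) stop("need at least 2 rows")
  if (k > min(M, D)) stop("k = ", k, " exceeds min(M, D) = ", min(M, D))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  comp <- t(pc$rotation[, seq_len(k), drop = FALSE])   # k x D
  coords <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(comp[j, ]))
    if (comp[j, i_max] < 0) {
      comp[j, ] <- -comp[j, ]
      coords[, j] <- -coords[, j]
    }
  }
  dimnames(coords) <- list(rownames(X), paste0("PC", seq_len(k)))
  structure(list(mean = pc$center,
                 components = comp,
                 explained_variance_ratio = pc$sdev[seq_len(k)]^2 / total_var,
                 coords = coords),
            class = "pca_result")
}

#' Correlation of principal-axis coordinates with a property
#'
#' Quantifies the color gradient seen when a PCA projection is shaded by a
#' molecular property.
#'
#' @param coords M x k coordinate matrix (e.g. `pca_result$coords`).
#' @param values Property vector of length M.
#' @return Named numeric vector of Pearson correlations, one per axis.
#' @export
property_gradient <- function(coords, values) {
  coords <- as.matrix(coords)
  stopifnot(length(values) == nrow(coords))
  if (stats::sd(values) == 0) stop("property has zero variance")
  stats::setNames(
    vapply(seq_len(ncol(coords)), function(j) stats::cor(coords[, j], values),
           numeric(1)),
    colnames(coords))
}

#' Exemplar molecules for a property
#'
#' @param mol_ids Identifiers.
#' @param values Property values, same length.
#' @return A list with `highest`, `lowest` and `closest_to_mean` ids; all
#'   ties are broken by `mol_id` order.
#' @export
select_exemplars <- function(mol_ids, values) {
  stopifnot(length(mol_ids) == length(values), length(mol_ids) > 0L)
  pick <- function(key) mol_ids[order(key, mol_ids)[1L]]
  list(highest = pick(-values),
       lowest = pick(values),
       closest_to_mean = pick(abs(values - mean(values))))
}

# deterministic integer hash of a string (polynomial rolling hash mod the
# Mersenne prime 2^31 - 1; exact in double arithmetic since intermediate
# values stay below 2^53)
str_hash <- function(s) {
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  h
}

#' Circular (Morgan-style) fingerprint
#'
#' Iterative neighborhood hashing: the initial atom invariant is the tuple
#' (element, degree, formal charge, H count, in-ring flag); each radius
#' iteration rehashes an atom's identifier together with the sorted
#' (bond-order, neighbor-identifier) list; all identifiers from radius 0 up
#' to `radius` are folded modulo `n_bits`. The construction is deterministic
#' and internally consistent, but bit values are implementation-specific
#' and will not match other toolkits.
#'
#' @param molecule SMILES string or `ring_mol`.
#' @param radius Neighborhood radius (default 3).
#' @param n_bits Fingerprint length (default 2048).
#' @return A list of class `fingerprint`: sorted unique `bits` (0-based),
#'   `n_bits`, `radius`.
#' @export
morgan_fingerprint <- function(molecule, radius = 3L, n_bits = 2048L) {
  mol <- if (inherits(molecule, "ring_mol")) molecule else {
    can <- canonical_smiles(molecule)
    if (is.na(can)) stop("unparseable SMILES: ", molecule)
    parse_smiles(can)
  }
  n <- nrow(mol$atoms)
  deg <- atom_degree(mol)
  rings <- mol_sssr(mol)
  in_ring <- logical(n)
  for (rg in rings) in_ring[rg] <- TRUE
  ids <- vapply(seq_len(n), function(i) {
    str_hash(paste(mol$atoms$element[i], deg[i], mol$atoms$charge[i],
                   mol$atoms$h[i], as.integer(in_ring[i]), sep = "|"))
  }, numeric(1))
  all_ids <- ids
  if (nrow(mol$bonds) > 0L && radius >= 1L) {
    nb <- vector("list", n)
    for (k in seq_len(nrow(mol$bonds))) {
      o <- if (mol$bonds$aromatic[k]) 4L else mol$bonds$order[k]
      nb[[mol$bonds$a1[k]]] <- rbind(nb[[mol$bonds$a1[k]]],
                                     c(o, mol$bonds$a2[k]))
      nb[[mol$bonds$a2[k]]] <- rbind(nb[[mol$bonds$a2[k]]],
                                     c(o, mol$bonds$a1[k]))
    }
    for (r in seq_len(radius)) {
      new_ids <- vapply(seq_len(n), function(i) {
        if (is.null(nb[[i]])) return(ids[i])
        pairs <- paste(nb[[i]][, 1L], ids[nb[[i]][, 2L]], sep = ":")
        str_hash(paste(c(r, ids[i], sort(pairs)), collapse = "|"))
      }, numeric(1))
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  structure(list(bits = sort(unique(as.integer(all_ids %% n_bits))),
                 n_bits = as.integer(n_bits), radius = as.integer(radius)),
            class = "fingerprint")
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both are empty.
#'
#' @param a,b `fingerprint` objects with equal `n_bits`.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$n_bits != b$n_bits) {
    stop("fingerprint length mismatch: ", a$n_bits, " vs ", b$n_bits)
  }
  un <- length(union(a$bits, b$bits))
  if (un == 0L) return(1)
  length(intersect(a$bits, b$bits)) / un
}

#' Maximum similarity of a molecule to a reference set
#'
#' Self-matches are excluded by id, so a molecule present in the reference
#' set under its own id is not compared with itself.
#'
#' @param mol_id,smiles Query molecule.
#' @param ref_records Reference records (`mol_id`, `smiles`).
#' @param radius,n_bits Fingerprint parameters.
#' @param ref_fps Optional precomputed list of reference fingerprints
#'   (named by `mol_id`), e.g. to amortize over many queries.
#' @return A list with `best_value` and `best_id` (ties broken by id).
#' @export
max_similarity_to_set <- function(mol_id, smiles, ref_records,
                                  radius = 3L, n_bits = 2048L,
                                  ref_fps = NULL) {
  stopifnot(nrow(ref_records) > 0L)
  fp <- morgan_fingerprint(smiles, radius, n_bits)
  if (is.null(ref_fps)) {
    ref_fps <- lapply(ref_records$smiles, morgan_fingerprint, radius = radius,
                      n_bits = n_bits)
    names(ref_fps) <- ref_records$mol_id
  }
  keep <- ref_records$mol_id != mol_id
  if (!any(keep)) return(list(best_value = NA_real_, best_id = NA_character_))
  sims <- vapply(which(keep), function(i) tanimoto(fp, ref_fps[[i]]),
                 numeric(1))
  ids <- ref_records$mol_id[keep]
  ord <- order(-sims, ids)
  list(best_value = sims[ord[1L]], best_id = ids[ord[1L]])
}

#' Histograms of the five properties
#'
#' @param properties Property data frame (columns `gap_eV`, `ip_eV`,
#'   `ea_eV`, `eox_V`, `ered_V`; `NA` rows are ignored per property).
#' @param bins Number of equal-width bins.
#' @return Named list per property: `counts`, `breaks`, `min`, `max`, `n`.
#' @export
property_histograms <- function(properties, bins = 30L) {
  cols <- intersect(PROPERTY_NAMES, names(properties))
  if (length(cols) == 0L) stop("no property columns found")
  out <- list()
  for (cl in cols) {
    v <- properties[[cl]]
    v <- v[is.finite(v)]
    if (length(v) == 0L) next
    if (min(v) == max(v)) {
      breaks <- c(min(v) - 0.5, min(v) + 0.5)
      counts <- length(v)
    } else {
      breaks <- seq(min(v), max(v), length.out = bins + 1L)
      h <- graphics::hist(v, breaks = breaks, plot = FALSE)
      counts <- h$counts
    }
    out[[cl]] <- list(counts = counts, breaks = breaks,
                      min = min(v), max = max(v), n = length(v))
  }
  out
}

#' Read / write an embedding matrix as CSV
#'
#' Format: `id` column followed by the numeric embedding columns.
#'
#' @param x An `embedding_matrix` (see [model_embeddings()]).
#' @param path CSV path.
#' @export
write_embeddings <- function(x, path) {
  df <- data.frame(id = x$mol_ids, x$X)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(mol_ids = as.character(df[[1L]]),
                 X = as.matrix(df[, -1L, drop = FALSE])),
            class = "embedding_matrix")
}
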