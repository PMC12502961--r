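# Molecular graph featurization: atoms are nodes, bonds are edges.
#
# The exact feature lists consumed by the regressor are versioned behind
# `feature_scheme()` so an alternative scheme can be swapped in without
# touching the model code.

#' Feature scheme for molecular graphs
#'
#' Node blocks (in order): element one-hot over the palette plus an unknown
#' slot; degree one-hot 0-5 (higher degrees clamp to the last bin);
#' formal-charge one-hot over \{-1, 0, +1\}; aromatic flag; in-ring flag;
#' ring-size flags for sizes 3-9 (multi-hot over the SSSR rings containing
#' the atom); hybridization one-hot \{sp, sp2, sp3, other\}; attached-H
#' one-hot 0-4. Edge blocks: bond-order one-hot \{single, double, triple,
#' aromatic\}; conjugated flag; in-ring flag.
#'
#' @param element_palette Ordered element symbols of the one-hot block.
#' @param version Scheme version string, stored in model checkpoints.
#' @return A list of class `feature_scheme`.
#' @export
feature_scheme <- function(element_palette = c("C", "N", "O", "S"),
                           version = "rp-node-v1/edge-v1") {
  stopifnot(length(element_palette) >= 1L, !anyDuplicated(element_palette))
  structure(list(element_palette = element_palette, version = version),
            class = "feature_scheme")
}

#' Feature dimensions of a scheme
#'
#' Pure function of the scheme: node width is palette size + 1 (unknown)
#' + 6 (degree) + 3 (charge) + 1 (aromatic) + 1 (in-ring) + 7 (ring sizes)
#' + 4 (hybridization) + 5 (H count); edge width is 4 (order) + 1
#' (conjugated) + 1 (in-ring).
#'
#' @param scheme A [feature_scheme()].
#' @return Integer vector `c(F_n, F_e)`.
#' @export
scheme_dims <- function(scheme) {
  stopifnot(inherits(scheme, "feature_scheme"))
  c(F_n = length(scheme$element_palette) + 1L + 6L + 3L + 1L + 1L + 7L +
      4L + 5L,
    F_e = 4L + 1L + 1L)
}

one_hot <- function(idx, width) {
  m <- matrix(0, length(idx), width)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Convert a molecule to an attributed graph
#'
#' The molecule is canonicalized first (unless `canonical = TRUE` asserts it
#' already is), so two SMILES spellings of the same molecule produce
#' identical graphs. Hydrogens stay implicit: nodes are heavy atoms only.
#' Each chemical bond yields two directed edges with identical features;
#' self-loops are not stored (the attention layer adds them internally).
#'
#' @param molecule SMILES string or `ring_mol`.
#' @param scheme A [feature_scheme()].
#' @param mol_id Identifier stored in the graph.
#' @param canonical If `TRUE`, skip re-canonicalization (the caller
#'   guarantees canonical input, e.g. records from [generate_molecules()]).
#' @return A list of class `molecular_graph`: `mol_id`, `node_features`
#'   (N x F_n), `edge_index` (E x 2 matrix of directed src, dst pairs),
#'   `edge_features` (E x F_e), `n_nodes`.
#' @export
featurize <- function(molecule, scheme = feature_scheme(), mol_id = NULL,
                      canonical = FALSE) {
  smi <- if (inherits(molecule, "ring_mol")) molecule$smiles else molecule
  if (!canonical) {
    can <- canonical_smiles(smi)
    if (is.na(can)) stop("unparseable SMILES: ", smi)
    smi <- can
  }
  mol <- parse_smiles(smi)
  n <- nrow(mol$atoms)
  pal <- scheme$element_palette

  el_idx <- match(mol$atoms$element, pal)
  if (anyNA(el_idx)) {
    warning("element(s) outside palette mapped to unknown slot: ",
            paste(unique(mol$atoms$element[is.na(el_idx)]), collapse = ", "))
    el_idx[is.na(el_idx)] <- length(pal) + 1L
  }
  deg <- atom_degree(mol)
  hyb <- atom_hybridization(mol)
  rings <- mol_sssr(mol)
  in_ring <- logical(n)
  ring_size_flags <- matrix(0, n, 7L)
  ring_edges <- character(0)
  for (rg in rings) {
    in_ring[rg] <- TRUE
    sz <- length(rg)
    if (sz >= 3L && sz <= 9L) ring_size_flags[rg, sz - 2L] <- 1
    for (t in seq_along(rg)) {
      a <- rg[t]; b <- rg[if (t == length(rg)) 1L else t + 1L]
      ring_edges <- c(ring_edges, paste(min(a, b), max(a, b)))
    }
  }

  node_features <- cbind(
    one_hot(el_idx, length(pal) + 1L),
    one_hot(pmin(deg, 5L) + 1L, 6L),
    one_hot(pmax(pmin(mol$atoms$charge, 1L), -1L) + 2L, 3L),
    as.numeric(mol$atoms$aromatic),
    as.numeric(in_ring),
    ring_size_flags,
    one_hot(match(hyb, c("sp", "sp2", "sp3"), nomatch = 4L), 4L),
    one_hot(pmin(mol$atoms$h, 4L) + 1L, 5L)
  )

  m <- nrow(mol$bonds)
  if (m > 0L) {
    bd <- mol$bonds
    order_idx <- ifelse(bd$aromatic, 4L,
                        ifelse(bd$order == 2L, 2L,
                               ifelse(bd$order == 3L, 3L, 1L)))
    conj <- bd$aromatic |
      (hyb[bd$a1] %in% c("sp", "sp2") & hyb[bd$a2] %in% c("sp", "sp2"))
    bond_in_ring <- paste(pmin(bd$a1, bd$a2), pmax(bd$a1, bd$a2)) %in%
      ring_edges
    ef <- cbind(one_hot(order_idx, 4L), as.numeric(conj),
                as.numeric(bond_in_ring))
    edge_index <- rbind(cbind(bd$a1, bd$a2), cbind(bd$a2, bd$a1))
    edge_features <- rbind(ef, ef)
  } else {
    edge_index <- matrix(integer(0), 0L, 2L)
    edge_features <- matrix(0, 0L, scheme_dims(scheme)[["F_e"]])
  }
  dimnames(edge_index) <- NULL

  structure(list(mol_id = if (is.null(mol_id)) smi else mol_id,
                 node_features = node_features,
                 edge_index = edge_index,
                 edge_features = edge_features,
                 n_nodes = n),
            class = "molecular_graph")
}

#' Featurize a whole record table
#'
#' @param records Molecule records with canonical `smiles` and `mol_id`.
#' @param scheme A [feature_scheme()].
#' @return A list of `molecular_graph` objects, named by `mol_id`.
#' @export
featurize_dataset <- function(records, scheme = feature_scheme()) {
  graphs <- lapply(seq_len(nrow(records)), function(i) {
    featurize(records$smiles[i], scheme, mol_id = records$mol_id[i],
              canonical = TRUE)
  })
  names(graphs) <- records$mol_id
  graphs
}
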