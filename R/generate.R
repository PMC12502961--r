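# Seeded generator of valid cyclic test molecules.
#
# Molecules are assembled from ring templates: ring skeletons are sampled
# (size, aromatic vs aliphatic), joined by a sampled connection type
# (fused / bridged / spiro / linked), then decorated with heteroatoms under
# valence checking. Assembly guarantees structural validity by construction;
# Open Babel canonicalization is the final validity gate and the basis for
# deduplication.

#' Configuration for the cyclic-molecule generator
#'
#' Defaults emulate the structural envelope of large mined ring-system
#' libraries: 1-3 rings per molecule with the mono/bi/tricyclic mixture
#' observed in such collections, ring sizes 3-9, and 3-24 heavy atoms.
#' Aromatic templates are restricted to 5- and 6-membered rings (the sizes
#' that admit neutral 4n+2 aromatics with standard atoms); all other sizes
#' are generated aliphatic.
#'
#' @param seed Integer RNG seed; generation is fully deterministic given it.
#' @param n_molecules Number of unique molecules to produce.
#' @param ring_count_weights Probabilities for 1/2/3 rings. The default is
#'   the mono/bi/tricyclic composition 15347:79777:106422 of a 201546-record
#'   ring-system library.
#' @param ring_size_range Inclusive ring-size bounds, within \[3, 9\].
#' @param element_palette Allowed element symbols. Default `C/N/O/S`;
#'   an extended set may add `B`, `F`, `Si`, `P`, `Se`, `I` (the monovalent
#'   `F`/`I` appear as exocyclic substituents, the rest as ring atoms).
#' @param connection_weights Probabilities over connection types
#'   `fused`, `bridged`, `spiro`, `linked` (single-bond "diaryl-like").
#' @param heteroatom_rate Per-position probability of heteroatom
#'   substitution.
#' @param saturation_rate Probability that a ring is aliphatic rather than
#'   aromatic (applies to sizes 5 and 6 only).
#' @param max_heavy_atoms Upper bound on heavy atoms per molecule.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_molecules = 100L,
                             ring_count_weights = c(15347, 79777, 106422) / 201546,
                             ring_size_range = c(3L, 9L),
                             element_palette = c("C", "N", "O", "S"),
                             connection_weights = c(fused = 0.40, bridged = 0.15,
                                                    spiro = 0.15, linked = 0.30),
                             heteroatom_rate = 0.15,
                             saturation_rate = 0.45,
                             max_heavy_atoms = 24L) {
  stopifnot(length(ring_count_weights) == 3L, all(ring_count_weights >= 0))
  if (abs(sum(ring_count_weights) - 1) > 1e-8) {
    stop("ring_count_weights must sum to 1")
  }
  stopifnot(length(connection_weights) == 4L, all(connection_weights >= 0))
  if (abs(sum(connection_weights) - 1) > 1e-8) {
    stop("connection_weights must sum to 1")
  }
  if (is.null(names(connection_weights))) {
    names(connection_weights) <- c("fused", "bridged", "spiro", "linked")
  }
  stopifnot(length(ring_size_range) == 2L,
            ring_size_range[1] >= 3L, ring_size_range[2] <= 9L,
            ring_size_range[1] <= ring_size_range[2])
  stopifnot(heteroatom_rate >= 0, heteroatom_rate <= 1,
            saturation_rate >= 0, saturation_rate <= 1,
            n_molecules >= 1L)
  bad <- setdiff(element_palette,
                 c("C", "N", "O", "S", "B", "F", "Si", "P", "Se", "I"))
  if (length(bad) > 0L) stop("unsupported palette elements: ",
                             paste(bad, collapse = ", "))
  if (!"C" %in% element_palette) stop("element_palette must contain C")
  structure(list(seed = as.integer(seed),
                 n_molecules = as.integer(n_molecules),
                 ring_count_weights = ring_count_weights,
                 ring_size_range = as.integer(ring_size_range),
                 element_palette = element_palette,
                 connection_weights = connection_weights,
                 heteroatom_rate = heteroatom_rate,
                 saturation_rate = saturation_rate,
                 max_heavy_atoms = as.integer(max_heavy_atoms)),
            class = "generator_config")
}

# --- assembly state helpers -------------------------------------------------
# `asm`: list(el, arom, nh (forced H or NA), b1, b2, barom, rings (list of
# atom index vectors))

asm_degree <- function(asm) {
  deg <- integer(length(asm$el))
  for (k in seq_along(asm$b1)) {
    deg[asm$b1[k]] <- deg[asm$b1[k]] + 1L
    deg[asm$b2[k]] <- deg[asm$b2[k]] + 1L
  }
  deg
}

asm_add_bond <- function(asm, a, b, arom) {
  asm$b1 <- c(asm$b1, a); asm$b2 <- c(asm$b2, b)
  asm$barom <- c(asm$barom, arom)
  asm
}

asm_new_atoms <- function(asm, k, arom) {
  idx <- length(asm$el) + seq_len(k)
  asm$el <- c(asm$el, rep("C", k))
  asm$arom <- c(asm$arom, rep(arom, k))
  asm$nh <- c(asm$nh, rep(NA_integer_, k))
  list(asm = asm, idx = idx)
}

# maximum heavy-atom degree an atom may reach
asm_capacity <- function(asm) {
  ifelse(asm$arom, 3L, 4L)
}

# one sampled ring system; returns asm or NULL on a dead end
assemble_molecule <- function(cfg) {
  rc <- sample.int(3L, 1L, prob = cfg$ring_count_weights)
  szr <- cfg$ring_size_range
  for (try in 1:20) {
    sizes <- sample(seq(szr[1], szr[2]), rc, replace = TRUE)
    if (sum(sizes) <= cfg$max_heavy_atoms + 2L * (rc - 1L)) break
    sizes <- NULL
  }
  if (is.null(sizes)) return(NULL)
  aromatic <- vapply(sizes, function(s) {
    s %in% c(5L, 6L) && stats::runif(1) > cfg$saturation_rate
  }, logical(1))

  # first ring
  asm <- list(el = character(0), arom = logical(0), nh = integer(0),
              b1 = integer(0), b2 = integer(0), barom = logical(0),
              rings = list())
  na <- asm_new_atoms(asm, sizes[1], aromatic[1]); asm <- na$asm
  ring <- na$idx
  for (t in seq_along(ring)) {
    asm <- asm_add_bond(asm, ring[t], ring[if (t == length(ring)) 1L else t + 1L],
                        aromatic[1])
  }
  asm$rings[[1]] <- ring

  if (rc > 1L) {
    for (r in 2:rc) {
      conn <- sample(names(cfg$connection_weights), 1L,
                     prob = cfg$connection_weights)
      asm2 <- attach_ring(asm, sizes[r], aromatic[r], conn)
      if (is.null(asm2)) {  # fall back to any feasible connection type
        for (alt in setdiff(c("fused", "linked", "spiro", "bridged"), conn)) {
          asm2 <- attach_ring(asm, sizes[r], aromatic[r], alt)
          if (!is.null(asm2)) break
        }
      }
      if (is.null(asm2)) return(NULL)
      asm <- asm2
    }
  }
  if (length(asm$el) > cfg$max_heavy_atoms || length(asm$el) < 3L) return(NULL)
  decorate_heteroatoms(asm, cfg)
}

attach_ring <- function(asm, size, aromatic, conn) {
  deg <- asm_degree(asm)
  cap <- asm_capacity(asm)
  switch(conn,
    fused = {
      if (size < 3L) return(NULL)
      # candidate shared bonds: C-C with spare valence on both ends; an
      # aromatic new ring needs both shared atoms to end at degree <= 3
      ok <- which(asm$el[asm$b1] == "C" & asm$el[asm$b2] == "C" &
                  deg[asm$b1] < cap[asm$b1] & deg[asm$b2] < cap[asm$b2] &
                  (!aromatic | (deg[asm$b1] <= 2L & deg[asm$b2] <= 2L)))
      if (length(ok) == 0L) return(NULL)
      k <- ok[sample.int(length(ok), 1L)]
      sa <- asm$b1[k]; sb <- asm$b2[k]
      if (aromatic) {
        asm$arom[c(sa, sb)] <- TRUE
        asm$barom[k] <- TRUE
      }
      na <- asm_new_atoms(asm, size - 2L, aromatic); asm <- na$asm
      path <- c(sa, na$idx, sb)
      for (t in seq_len(length(path) - 1L)) {
        asm <- asm_add_bond(asm, path[t], path[t + 1L], aromatic)
      }
      asm$rings[[length(asm$rings) + 1L]] <- path
      asm
    },
    spiro = {
      # spiro centre must be sp3 carbon: force the new ring aliphatic
      ok <- which(asm$el == "C" & !asm$arom & deg == 2L)
      if (length(ok) == 0L) return(NULL)
      sp <- ok[sample.int(length(ok), 1L)]
      na <- asm_new_atoms(asm, size - 1L, FALSE); asm <- na$asm
      path <- c(sp, na$idx)
      for (t in seq_len(length(path) - 1L)) {
        asm <- asm_add_bond(asm, path[t], path[t + 1L], FALSE)
      }
      asm <- asm_add_bond(asm, path[length(path)], sp, FALSE)
      asm$rings[[length(asm$rings) + 1L]] <- path
      asm
    },
    linked = {
      ok <- which(asm$el == "C" & deg < cap)
      if (length(ok) == 0L) return(NULL)
      anchor <- ok[sample.int(length(ok), 1L)]
      na <- asm_new_atoms(asm, size, aromatic); asm <- na$asm
      ring <- na$idx
      for (t in seq_along(ring)) {
        asm <- asm_add_bond(asm, ring[t], ring[if (t == length(ring)) 1L else t + 1L],
                            aromatic)
      }
      asm <- asm_add_bond(asm, anchor, ring[1], FALSE)  # single biaryl-type link
      asm$rings[[length(asm$rings) + 1L]] <- ring
      asm
    },
    bridged = {
      # bridge two non-adjacent sp3 carbons of an existing aliphatic ring
      cands <- Filter(function(rg) {
        sum(!asm$arom[rg] & asm$el[rg] == "C" & deg[rg] <= 3L) >= 2L &&
          length(rg) >= 4L
      }, asm$rings)
      if (length(cands) == 0L) return(NULL)
      rg <- cands[[sample.int(length(cands), 1L)]]
      pos <- which(!asm$arom[rg] & asm$el[rg] == "C" & deg[rg] <= 3L)
      pairs <- list()
      for (i in pos) for (j in pos) {
        if (j <= i) next
        arc <- min(j - i, length(rg) - (j - i))
        if (arc >= 2L) pairs[[length(pairs) + 1L]] <- c(i, j, arc)
      }
      if (length(pairs) == 0L) return(NULL)
      pr <- pairs[[sample.int(length(pairs), 1L)]]
      klen <- max(1L, min(3L, size - 2L - pr[3]))
      if (klen + 2L + pr[3] > 9L) klen <- 1L
      if (klen + 2L + pr[3] > 9L) return(NULL)
      a <- rg[pr[1]]; b <- rg[pr[2]]
      na <- asm_new_atoms(asm, klen, FALSE); asm <- na$asm
      path <- c(a, na$idx, b)
      for (t in seq_len(length(path) - 1L)) {
        asm <- asm_add_bond(asm, path[t], path[t + 1L], FALSE)
      }
      asm$rings[[length(asm$rings) + 1L]] <- path
      asm
    },
    stop("unknown connection type: ", conn))
}

# heteroatom substitution and optional halogen decoration, valence-checked
decorate_heteroatoms <- function(asm, cfg) {
  pal <- cfg$element_palette
  deg <- asm_degree(asm)
  nbrs <- function(i) {
    c(asm$b2[asm$b1 == i], asm$b1[asm$b2 == i])
  }
  het_adjacent <- function(i) any(asm$el[nbrs(i)] != "C")
  ring_membership <- integer(length(asm$el))
  for (rg in asm$rings) ring_membership[rg] <- ring_membership[rg] + 1L

  # aromatic 5-rings need one two-electron donor (furan/thiophene/pyrrole
  # type); without one the ring cannot be a neutral aromatic system
  for (ri in seq_along(asm$rings)) {
    rg <- asm$rings[[ri]]
    if (length(rg) != 5L || !all(asm$arom[rg])) next
    donors <- intersect(pal, c("O", "S", "Se", "N"))
    free <- rg[deg[rg] == 2L & asm$el[rg] == "C" & ring_membership[rg] == 1L]
    free <- free[!vapply(free, het_adjacent, logical(1))]
    if (length(donors) == 0L || length(free) == 0L) {
      # cannot aromatize: demote ring and its private bonds to aliphatic
      asm$arom[rg[ring_membership[rg] == 1L]] <- FALSE
      for (k in seq_along(asm$b1)) {
        if (asm$b1[k] %in% rg && asm$b2[k] %in% rg &&
            !(asm$arom[asm$b1[k]] && asm$arom[asm$b2[k]])) {
          asm$barom[k] <- FALSE
        }
      }
      next
    }
    pick <- free[sample.int(length(free), 1L)]
    el <- donors[sample.int(length(donors), 1L)]
    asm$el[pick] <- el
    if (el == "N") asm$nh[pick] <- 1L  # pyrrole-type NH
  }

  # probabilistic substitution elsewhere (never two adjacent heteroatoms,
  # never at ring-junction atoms)
  for (i in seq_along(asm$el)) {
    if (asm$el[i] != "C" || ring_membership[i] != 1L) next
    if (het_adjacent(i)) next
    if (stats::runif(1) >= cfg$heteroatom_rate) next
    if (asm$arom[i]) {
      if (deg[i] == 2L && "N" %in% pal) asm$el[i] <- "N"  # pyridine-type
    } else if (deg[i] == 2L) {
      opts <- intersect(pal, c("N", "O", "S", "Si", "P", "Se", "B"))
      if (length(opts) > 0L) {
        el <- opts[sample.int(length(opts), 1L)]
        asm$el[i] <- el
        if (el == "Si") asm$nh[i] <- 2L
        if (el == "Se") asm$nh[i] <- 0L
      }
    } else if (deg[i] == 3L) {
      opts <- intersect(pal, c("N", "P", "B"))
      if (length(opts) > 0L) asm$el[i] <- opts[sample.int(length(opts), 1L)]
    }
  }

  # exocyclic halogens (extended palette only)
  halo <- intersect(pal, c("F", "I"))
  if (length(halo) > 0L) {
    deg <- asm_degree(asm)
    cap <- asm_capacity(asm)
    for (i in seq_along(asm$el)) {
      if (length(asm$el) >= cfg$max_heavy_atoms) break
      if (asm$el[i] != "C" || deg[i] >= cap[i]) next
      if (stats::runif(1) >= cfg$heteroatom_rate / 3) next
      el <- halo[sample.int(length(halo), 1L)]
      asm$el <- c(asm$el, el); asm$arom <- c(asm$arom, FALSE)
      asm$nh <- c(asm$nh, 0L)
      asm <- asm_add_bond(asm, i, length(asm$el), FALSE)
      deg[i] <- deg[i] + 1L
    }
  }
  asm
}

# serialize an assembly to SMILES (DFS spanning tree + ring-closure digits)
asm_to_smiles <- function(asm) {
  n <- length(asm$el)
  m <- length(asm$b1)
  adj <- rep(list(integer(0)), n)   # bond indices per atom
  for (k in seq_len(m)) {
    adj[[asm$b1[k]]] <- c(adj[[asm$b1[k]]], k)
    adj[[asm$b2[k]]] <- c(adj[[asm$b2[k]]], k)
  }
  other <- function(k, i) if (asm$b1[k] == i) asm$b2[k] else asm$b1[k]

  visited <- logical(n); used <- logical(m)
  closure_of <- rep(list(list()), n)  # atom -> list of (digit, bond)
  next_digit <- 0L
  # first pass: mark spanning tree, assign closure digits
  order_stack <- list(list(atom = 1L, from = 0L))
  tree_children <- rep(list(integer(0)), n)
  visited[1L] <- TRUE
  dfs <- function(i) {
    for (k in adj[[i]]) {
      if (used[k]) next
      j <- other(k, i)
      if (!visited[j]) {
        used[k] <<- TRUE
        visited[j] <<- TRUE
        tree_children[[i]] <<- c(tree_children[[i]], k)
        dfs(j)
      } else {
        used[k] <<- TRUE
        next_digit <<- next_digit + 1L
        d <- next_digit
        closure_of[[i]] <<- c(closure_of[[i]], list(list(digit = d, bond = k)))
        closure_of[[j]] <<- c(closure_of[[j]], list(list(digit = d, bond = k)))
      }
    }
  }
  dfs(1L)
  if (!all(visited)) stop("internal error: disconnected assembly")

  atom_token <- function(i) {
    el <- asm$el[i]
    if (asm$arom[i]) {
      if (el == "N" && !is.na(asm$nh[i]) && asm$nh[i] > 0L) return("[nH]")
      if (el == "Se") return("[se]")
      return(tolower(el))
    }
    if (el == "Si") return(paste0("[SiH", asm$nh[i], "]"))
    if (el == "Se") return("[Se]")
    el
  }
  bond_token <- function(k) {
    if (asm$barom[k]) return("")
    if (asm$arom[asm$b1[k]] && asm$arom[asm$b2[k]]) return("-")
    ""
  }
  emit <- function(i) {
    s <- atom_token(i)
    for (cl in closure_of[[i]]) {
      d <- cl$digit
      dd <- if (d > 9L) sprintf("%%%02d", d) else as.character(d)
      s <- paste0(s, bond_token(cl$bond), dd)
    }
    kids <- tree_children[[i]]
    if (length(kids) > 0L) {
      for (t in seq_along(kids)) {
        k <- kids[t]
        sub <- paste0(bond_token(k), emit(other(k, i)))
        s <- if (t < length(kids)) paste0(s, "(", sub, ")")
             else paste0(s, sub)
      }
    }
    s
  }
  emit(1L)
}

#' Generate cyclic test molecules
#'
#' Draws `config$n_molecules` unique, valence-valid cyclic molecules by
#' template assembly. Output is deterministic given the config (including
#' its seed); uniqueness is by canonical-SMILES equality.
#'
#' @param config A [generator_config()].
#' @return A data frame of molecule records with columns `mol_id`, `smiles`
#'   (canonical), `ring_count`, `heavy_atom_count`, and a list column
#'   `elements` of named element-count vectors.
#' @export
generate_molecules <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_molecules
  got <- character(0)
  attempts <- 0L
  max_attempts <- 60L * n
  while (length(got) < n) {
    want <- n - length(got)
    batch_n <- max(20L, ceiling(want * 1.4))
    raw <- character(0)
    while (length(raw) < batch_n && attempts < max_attempts) {
      attempts <- attempts + 1L
      asm <- assemble_molecule(config)
      if (!is.null(asm)) raw <- c(raw, asm_to_smiles(asm))
    }
    if (length(raw) > 0L) {
      can <- canonical_smiles(raw)
      can <- unique(can[!is.na(can)])
      if (length(can) > 0L) {
        # keep only idempotently canonical strings (rare borderline aromatic
        # systems can flip perception on a second pass) that the in-package
        # parser also handles
        can2 <- canonical_smiles(can)
        keep <- !is.na(can2) & can2 == can
        keep <- keep & vapply(can, function(s) {
          !is.null(tryCatch(parse_smiles(s), error = function(e) NULL))
        }, logical(1))
        got <- c(got, setdiff(can[keep], got))
      }
    }
    if (attempts >= max_attempts && length(got) < n) {
      stop("generator exhausted ", max_attempts, " attempts with only ",
           length(got), " unique molecules; the configuration is ",
           "over-constrained")
    }
  }
  got <- got[seq_len(n)]
  mols <- lapply(got, parse_smiles)
  data.frame(
    mol_id = sprintf("RP%06d", seq_len(n)),
    smiles = got,
    ring_count = vapply(mols, count_rings, integer(1)),
    heavy_atom_count = vapply(mols, n_atoms, integer(1)),
    elements = I(lapply(mols, element_counts)),
    stringsAsFactors = FALSE
  )
}

PROPERTY_COLUMNS <- c("gap_eV", "ip_eV", "ea_eV", "eox_V", "ered_V")

#' Read a SMILES + property table
#'
#' Expects a CSV with header `id,smiles,gap_eV,ip_eV,ea_eV,eox_V,ered_V`.
#' Property cells may be empty (unlabeled molecules). Duplicate ids or
#' unparseable SMILES raise an error naming the offenders.
#'
#' @param path CSV file path.
#' @return A list with `records` (molecule records data frame, row order as
#'   in the file) and `properties` (data frame keyed by `mol_id` with the
#'   five property columns; `NA` marks missing labels).
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character", smiles = "character"))
  need <- c("id", "smiles", PROPERTY_COLUMNS)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup) > 0L) {
    stop("duplicate id(s): ", paste(dup, collapse = ", "))
  }
  can <- canonical_smiles(df$smiles)
  if (anyNA(can)) {
    stop("unparseable SMILES at row(s): ",
         paste(which(is.na(can)), collapse = ", "),
         " (", paste(df$smiles[is.na(can)], collapse = "; "), ")")
  }
  mols <- lapply(can, parse_smiles)
  records <- data.frame(
    mol_id = df$id,
    smiles = can,
    ring_count = vapply(mols, count_rings, integer(1)),
    heavy_atom_count = vapply(mols, n_atoms, integer(1)),
    elements = I(lapply(mols, element_counts)),
    stringsAsFactors = FALSE
  )
  properties <- data.frame(mol_id = df$id, stringsAsFactors = FALSE)
  for (cl in PROPERTY_COLUMNS) properties[[cl]] <- as.numeric(df[[cl]])
  list(records = records, properties = properties)
}

#' Write a SMILES + property table
#'
#' Inverse of [read_dataset()]: emits UTF-8 comma-separated text with a
#' mandatory header and `.` decimals. Numeric values are printed with 15
#' significant digits so a write/read round trip reproduces them.
#'
#' @param records Molecule records (needs `mol_id`, `smiles`).
#' @param properties Optional property data frame keyed by `mol_id`.
#' @param path Output CSV path.
#' @export
write_dataset <- function(records, properties = NULL, path) {
  out <- data.frame(id = records$mol_id, smiles = records$smiles,
                    stringsAsFactors = FALSE)
  for (cl in PROPERTY_COLUMNS) {
    vals <- rep(NA_real_, nrow(out))
    if (!is.null(properties) && cl %in% names(properties)) {
      vals <- properties[[cl]][match(records$mol_id, properties$mol_id)]
    }
    out[[cl]] <- ifelse(is.na(vals), "", sprintf("%.15g", vals))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarize a molecule set
#'
#' @param records Molecule records from [generate_molecules()] or
#'   [read_dataset()].
#' @return A list of class `dataset_summary`: `n`, `ring_composition`
#'   (counts for 1/2/3+ rings), `element_hist` (total heavy-atom counts per
#'   element) and `heavy_atom_hist` (molecules per heavy-atom count).
#' @export
dataset_summary <- function(records) {
  stopifnot(nrow(records) > 0L)
  ring_comp <- table(factor(records$ring_count,
                            levels = sort(unique(records$ring_count))))
  el <- records$elements
  if (is.null(el)) el <- lapply(records$smiles, element_counts)
  all_el <- sort(unique(unlist(lapply(el, names))))
  el_hist <- stats::setNames(numeric(length(all_el)), all_el)
  for (e in el) el_hist[names(e)] <- el_hist[names(e)] + e
  structure(list(
    n = nrow(records),
    ring_composition = ring_comp,
    element_hist = el_hist,
    heavy_atom_hist = table(records$heavy_atom_count)
  ), class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat("Dataset of", x$n, "molecules\n")
  cat("  ring composition:\n")
  print(x$ring_composition)
  cat("  element totals:\n")
  print(x$element_hist)
  invisible(x)
}
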