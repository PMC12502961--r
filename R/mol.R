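# Internal molecular graph representation and SMILES I/O.
#
# Molecules are stored as a light S3 object ("ring_mol") holding an atom
# table (element, aromatic flag, formal charge, implicit H count) and a bond
# table (endpoints, order, aromatic flag). Hydrogens are implicit; all
# indices refer to heavy atoms. The SMILES dialect covered is the organic
# subset plus bracket atoms, branches, ring closures (including %nn) and
# explicit bond symbols - = # : (stereo markers are accepted and ignored).

STD_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                 S = 2, Se = 2, Cl = 1, Br = 1, I = 1)

# Elements that may appear lowercase (aromatic) in SMILES
AROMATIC_ELEMENTS <- c("b", "c", "n", "o", "p", "s", "se")

#' Parse a SMILES string into an internal molecular graph
#'
#' Supports the organic subset (`B C N O P S F Cl Br I`), aromatic lowercase
#' atoms, bracket atoms with explicit hydrogen counts and formal charges,
#' branches, and ring-bond closures. A bond written without a symbol between
#' two aromatic atoms is aromatic only if it lies in a ring (so the biaryl
#' linker bond in e.g. `c1ccc(-c2ccccc2)cc1` stays single even when the `-`
#' is omitted). Multi-component SMILES (containing `.`) are rejected.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `ring_mol` with elements `atoms` (data frame:
#'   `element`, `aromatic`, `charge`, `h`), `bonds` (data frame: `a1`, `a2`,
#'   `order`, `aromatic`) and `smiles` (the input string).
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("'smiles' must be a single non-empty string")
  }
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)

  element <- character(0); aromatic <- logical(0)
  charge <- integer(0); h_expl <- integer(0)      # NA_integer_ = implicit
  b_a1 <- integer(0); b_a2 <- integer(0)
  b_sym <- character(0)                           # "", "-", "=", "#", ":"

  prev <- NA_integer_
  stack <- integer(0)
  pending <- ""                                   # pending bond symbol
  ring_open <- list()                             # key -> list(atom, sym)

  add_atom <- function(el, arom, chg, h) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    h_expl[length(h_expl) + 1L] <<- h
    idx <- length(element)
    if (!is.na(prev)) {
      b_a1[length(b_a1) + 1L] <<- prev
      b_a2[length(b_a2) + 1L] <<- idx
      b_sym[length(b_sym) + 1L] <<- pending
    }
    prev <<- idx
    pending <<- ""
    idx
  }

  close_ring <- function(key) {
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      sym <- pending
      if (sym == "") sym <- op$sym
      if (op$sym != "" && pending != "" && op$sym != pending) {
        stop("conflicting bond symbols on ring closure in: ", smiles)
      }
      b_a1[length(b_a1) + 1L] <<- op$atom
      b_a2[length(b_a2) + 1L] <<- prev
      b_sym[length(b_sym) + 1L] <<- sym
      ring_open[[key]] <<- NULL
      pending <<- ""
    } else {
      ring_open[[key]] <<- list(atom = prev, sym = pending)
      pending <<- ""
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == ".") stop("multi-component SMILES not supported: ", smiles)
    if (ch %in% c("-", "=", "#", ":")) {
      pending <- ch; i <- i + 1L; next
    }
    if (ch %in% c("/", "\\")) { i <- i + 1L; next }  # stereo bond: as single
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L; next }
    if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in: ", smiles)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (grepl("[0-9]", ch)) { close_ring(ch); i <- i + 1L; next }
    if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring closure in: ", smiles)
      close_ring(paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 3L; next
    }
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket atom in: ", smiles)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-]+[0-9]*|[+-][0-9]*)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L) stop("cannot parse bracket atom [", body, "] in: ", smiles)
      sym <- m[3]
      arom <- sym %in% AROMATIC_ELEMENTS
      el <- if (arom) {
        paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      } else sym
      if (!el %in% names(STD_VALENCE)) {
        stop("unsupported element '", el, "' in: ", smiles)
      }
      hh <- m[5]
      h <- if (is.na(hh) || hh == "") 0L
           else if (hh == "H") 1L
           else as.integer(substring(hh, 2))
      cs <- m[6]
      chg <- 0L
      if (!is.na(cs) && nzchar(cs)) {
        sign <- if (substr(cs, 1, 1) == "+") 1L else -1L
        digits <- gsub("[+-]", "", cs)
        chg <- if (nzchar(digits)) sign * as.integer(digits)
               else sign * nchar(gsub("[^+-]", "", cs))
      }
      add_atom(el, arom, chg, h)
      i <- j + 1L; next
    }
    # organic-subset atom, possibly two letters (Cl, Br)
    if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r")) {
      two <- paste0(ch, chars[i + 1L])
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, 0L, NA_integer_)
        i <- i + 2L; next
      }
    }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, FALSE, 0L, NA_integer_)
      i <- i + 1L; next
    }
    if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE, 0L, NA_integer_)
      i <- i + 1L; next
    }
    stop("unexpected character '", ch, "' in: ", smiles)
  }
  if (length(ring_open) > 0L) stop("unclosed ring bond in: ", smiles)
  if (length(stack) > 0L) stop("unbalanced '(' in: ", smiles)
  if (length(element) == 0L) stop("no atoms in: ", smiles)

  order <- ifelse(b_sym == "=", 2L, ifelse(b_sym == "#", 3L, 1L))
  # aromatic if explicitly ':' or default bond between two aromatic atoms
  arom_bond <- b_sym == ":" |
    (b_sym == "" & aromatic[b_a1] & aromatic[b_a2])
  bonds <- data.frame(a1 = b_a1, a2 = b_a2, order = order,
                      aromatic = arom_bond)

  # default aromatic-aromatic bonds are aromatic only when cyclic
  cand <- which(bonds$aromatic & b_sym == "")
  if (length(cand) > 0L) {
    in_ring <- vapply(cand, function(k) {
      bond_in_cycle(bonds, length(element), k)
    }, logical(1))
    bonds$aromatic[cand[!in_ring]] <- FALSE
  }

  mol <- structure(list(
    atoms = data.frame(element = element, aromatic = aromatic,
                       charge = charge, h = h_expl),
    bonds = bonds,
    smiles = smiles
  ), class = "ring_mol")
  mol$atoms$h <- implicit_h(mol)
  mol
}

# TRUE if bond k of `bonds` lies on a cycle (endpoints stay connected
# after removing it)
bond_in_cycle <- function(bonds, n_atoms, k) {
  a <- bonds$a1[k]; b <- bonds$a2[k]
  adj <- adjacency_list(bonds[-k, , drop = FALSE], n_atoms)
  seen <- logical(n_atoms); seen[a] <- TRUE
  queue <- a
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        if (w == b) return(TRUE)
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  FALSE
}

adjacency_list <- function(bonds, n_atoms) {
  adj <- rep(list(integer(0)), n_atoms)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], bonds$a2[k])
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], bonds$a1[k])
  }
  adj
}

# Implicit hydrogen counts. Bracket atoms keep their explicit count
# (SMILES semantics: unspecified H in brackets means zero). For the rest,
# H = valence(+charge) - sigma bonds - 1 extra for aromatic C/N (their
# kekule double bond); aromatic O/S/Se contribute both lone-pair electrons
# and get no extra.
implicit_h <- function(mol) {
  at <- mol$atoms
  h <- at$h
  deg_order <- numeric(nrow(at))
  for (k in seq_len(nrow(mol$bonds))) {
    o <- if (mol$bonds$aromatic[k]) 1 else mol$bonds$order[k]
    deg_order[mol$bonds$a1[k]] <- deg_order[mol$bonds$a1[k]] + o
    deg_order[mol$bonds$a2[k]] <- deg_order[mol$bonds$a2[k]] + o
  }
  for (i in seq_len(nrow(at))) {
    if (!is.na(h[i])) next
    val <- STD_VALENCE[[at$element[i]]] + at$charge[i]
    extra <- if (at$aromatic[i] && at$element[i] %in% c("C", "N")) 1 else 0
    h[i] <- max(0L, as.integer(val - deg_order[i] - extra))
  }
  as.integer(h)
}

#' Number of heavy atoms in a molecule
#' @param mol A `ring_mol` object.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

# heavy-atom degree vector
atom_degree <- function(mol) {
  deg <- integer(nrow(mol$atoms))
  tab <- table(c(mol$bonds$a1, mol$bonds$a2))
  deg[as.integer(names(tab))] <- as.integer(tab)
  deg
}

# Hybridization per heavy atom: "sp" (triple bond or >=2 double bonds),
# "sp2" (aromatic or one double bond), else "sp3".
atom_hybridization <- function(mol) {
  nd <- integer(nrow(mol$atoms)); nt <- integer(nrow(mol$atoms))
  bd <- mol$bonds
  for (k in seq_len(nrow(bd))) {
    if (bd$aromatic[k]) next
    if (bd$order[k] == 2L) {
      nd[bd$a1[k]] <- nd[bd$a1[k]] + 1L; nd[bd$a2[k]] <- nd[bd$a2[k]] + 1L
    } else if (bd$order[k] == 3L) {
      nt[bd$a1[k]] <- nt[bd$a1[k]] + 1L; nt[bd$a2[k]] <- nt[bd$a2[k]] + 1L
    }
  }
  ifelse(nt > 0L | nd >= 2L, "sp",
         ifelse(mol$atoms$aromatic | nd == 1L, "sp2", "sp3"))
}

n_components <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- adjacency_list(mol$bonds, n)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

#' Count rings of a molecule
#'
#' Returns the size of the smallest set of smallest rings, which for
#' connected molecular graphs equals the cycle rank
#' (bonds - atoms + components).
#'
#' @param smiles A SMILES string (or a parsed `ring_mol`).
#' @return Integer ring count.
#' @examples
#' count_rings("c1ccccc1")          # 1
#' count_rings("c1ccc2ccccc2c1")    # 2
#' @export
count_rings <- function(smiles) {
  mol <- if (inherits(smiles, "ring_mol")) smiles else parse_smiles(smiles)
  nrow(mol$bonds) - nrow(mol$atoms) + max(n_components(mol))
}

# Smallest set of smallest rings via a Horton-style minimum cycle basis:
# enumerate candidate shortest cycles through every (vertex, edge) pair and
# greedily keep those independent over GF(2) on the edge space. Returns a
# list of integer atom-index vectors (in ring order).
mol_sssr <- function(mol) {
  n <- nrow(mol$atoms)
  bd <- mol$bonds
  m <- nrow(bd)
  rank_needed <- m - n + max(n_components(mol))
  if (rank_needed <= 0L) return(list())
  adj <- adjacency_list(bd, n)
  edge_id <- matrix(0L, n, n)
  for (k in seq_len(m)) {
    edge_id[bd$a1[k], bd$a2[k]] <- k
    edge_id[bd$a2[k], bd$a1[k]] <- k
  }
  # BFS trees from every vertex
  dist <- matrix(NA_integer_, n, n); parent <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.na(dist[s, w])) {
          dist[s, w] <- dist[s, v] + 1L
          parent[s, w] <- v
          queue <- c(queue, w)
        }
      }
    }
  }
  path_to <- function(s, v) {
    p <- v
    while (v != s) { v <- parent[s, v]; p <- c(p, v) }
    p  # v .. s
  }
  cycles <- list(); seen_keys <- character(0)
  for (s in seq_len(n)) {
    for (k in seq_len(m)) {
      x <- bd$a1[k]; y <- bd$a2[k]
      if (is.na(dist[s, x]) || is.na(dist[s, y])) next
      px <- path_to(s, x); py <- path_to(s, y)
      # internally vertex-disjoint except at s
      if (length(intersect(px[-length(px)], py[-length(py)])) > 0L) next
      cyc <- c(rev(px), py[-length(py)])  # s..x, y..(before s)
      if (length(cyc) < 3L || anyDuplicated(cyc)) next
      key <- paste(sort(cyc), collapse = ",")
      if (key %in% seen_keys) next
      seen_keys <- c(seen_keys, key)
      cycles[[length(cycles) + 1L]] <- cyc
    }
  }
  cycles <- cycles[order(vapply(cycles, length, integer(1)))]
  # greedy GF(2) independence on edge incidence vectors
  basis <- list(); sel <- list()
  for (cyc in cycles) {
    vec <- logical(m)
    for (t in seq_along(cyc)) {
      a <- cyc[t]; b <- cyc[if (t == length(cyc)) 1L else t + 1L]
      vec[edge_id[a, b]] <- TRUE
    }
    red <- vec
    for (bv in basis) {
      pivot <- which(bv)[1L]
      if (red[pivot]) red <- xor(red, bv)
    }
    if (any(red)) {
      basis[[length(basis) + 1L]] <- red
      sel[[length(sel) + 1L]] <- cyc
      if (length(sel) == rank_needed) break
    }
  }
  sel
}

#' Canonicalize SMILES strings
#'
#' Uses Open Babel (via \pkg{ChemmineOB}) to produce canonical aromatic
#' SMILES. Vectorized; strings that fail to parse yield `NA` (or an error
#' when `strict = TRUE`).
#'
#' @param smiles Character vector of SMILES.
#' @param strict Error on unparseable input instead of returning `NA`.
#' @return Character vector of canonical SMILES, same length as the input.
#' @export
canonical_smiles <- function(smiles, strict = FALSE) {
  if (length(smiles) == 0L) return(character(0))
  # tag with the input index so dropped (invalid) lines can be detected
  payload <- paste0(smiles, " ", seq_along(smiles), collapse = "\n")
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(payload, "\n")),
    error = function(e) "")
  res <- rep(NA_character_, length(smiles))
  if (nzchar(out)) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) >= 2L) {
        idx <- suppressWarnings(as.integer(trimws(p[2L])))
        if (!is.na(idx) && idx >= 1L && idx <= length(smiles)) {
          res[idx] <- p[1L]
        }
      }
    }
  }
  # Open Babel aborts a batch at the first bad line; retry stragglers singly
  if (anyNA(res) && length(smiles) > 1L) {
    for (idx in which(is.na(res))) {
      res[idx] <- canonical_smiles(smiles[idx])
    }
  }
  if (strict && anyNA(res)) {
    stop("unparseable SMILES: ",
         paste(smiles[is.na(res)], collapse = ", "))
  }
  res
}

#' Element counts of a molecule
#' @param mol A `ring_mol` or SMILES string.
#' @return Named integer vector of heavy-atom element counts.
#' @export
element_counts <- function(mol) {
  if (!inherits(mol, "ring_mol")) mol <- parse_smiles(mol)
  tab <- table(mol$atoms$element)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.ring_mol <- function(x, ...) {
  cat("<ring_mol> ", x$smiles, "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms), ", bonds: ", nrow(x$bonds),
      ", rings: ", count_rings(x), "\n", sep = "")
  invisible(x)
}
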