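# Hueckel molecular-orbital label oracle.
#
# Labels generated molecules with physically structured synthetic values:
# the conjugated pi system is extracted from the 2D graph, its tight-binding
# Hamiltonian H = alpha*I + beta*C is diagonalized (C carries the
# dimensionless heteroatom corrections h_X on the diagonal and bond factors
# k_XY off it), and frontier-orbital energies give gap / IP / EA via the
# Koopmans approximation. Redox labels are planted linear maps of IP and EA
# with optional Gaussian noise. Molecules without a pi system fall back to a
# documented group-contribution table.

#' Parameters of the Hueckel label oracle
#'
#' `alpha` and `beta` are the Coulomb and resonance integrals in eV; the
#' defaults (-6.6, -2.7) put benzene's Koopmans ionization potential at a
#' realistic 9.3 eV. Heteroatom corrections follow the standard Streitwieser
#' convention: the effective Coulomb integral of atom X is
#' `alpha + h_X * beta` and the resonance integral of bond X-Y is
#' `k_XY * beta`. Each heteroatom has an `one`-electron (pyridine-like) and
#' a `two`-electron (pyrrole/furan-like donor) context.
#'
#' @param alpha Coulomb integral, eV.
#' @param beta Resonance integral, eV; must be negative.
#' @param h_table Named list of per-element `c(one=, two=)` corrections.
#' @param k_table Named numeric vector of bond resonance factors, keyed by
#'   sorted element pair ("C-N"); `k_default` covers unlisted pairs.
#' @param k_default Fallback resonance factor.
#' @param sigma_default_gap Base HOMO-LUMO gap (eV) for molecules with no
#'   pi system, before heteroatom corrections.
#' @param sigma_gap_corr,sigma_ip_corr Named per-heteroatom additive
#'   corrections (eV per atom) of the sigma-only group-contribution model.
#' @param sigma_ip_base,sigma_ip_size Intercept and heavy-atom-count slope
#'   of the sigma-only ionization potential (eV).
#' @param ox_slope,ox_intercept,red_slope,red_intercept Planted linear maps
#'   `eox = ox_slope*IP + ox_intercept` and `ered = red_slope*EA +
#'   red_intercept` (V).
#' @param noise_sd Gaussian noise added to the redox labels, V.
#' @return A list of class `huckel_params`.
#' @export
huckel_params <- function(alpha = -6.6, beta = -2.7,
                          h_table = list(
                            C  = c(one = 0.0,  two = 0.0),
                            N  = c(one = 0.5,  two = 1.5),
                            O  = c(one = 1.0,  two = 2.0),
                            S  = c(one = 0.4,  two = 1.3),
                            Se = c(one = 0.3,  two = 1.1),
                            P  = c(one = 0.75, two = 1.5),
                            B  = c(one = -1.0, two = -1.0),
                            Si = c(one = 0.0,  two = 0.0)),
                          k_table = c("C-C" = 1.0, "C-N" = 0.8, "C-O" = 0.8,
                                      "C-S" = 0.7, "C-Se" = 0.6, "C-P" = 0.7,
                                      "B-C" = 0.7, "C-Si" = 0.75),
                          k_default = 0.7,
                          sigma_default_gap = 11.0,
                          sigma_gap_corr = c(N = -0.25, O = -0.15, S = -0.6,
                                             Si = -0.5, P = -0.45, Se = -0.7,
                                             B = -0.35, F = 0.2, I = -0.9),
                          sigma_ip_base = 11.0, sigma_ip_size = 0.12,
                          sigma_ip_corr = c(N = 0.5, O = 0.3, S = 0.9,
                                            Si = 0.6, P = 0.7, Se = 1.0,
                                            B = 0.2, F = -0.4, I = 0.8),
                          ox_slope = 0.92, ox_intercept = -4.9,
                          red_slope = -0.95, red_intercept = 1.1,
                          noise_sd = 0.15) {
  stopifnot(beta < 0, sigma_default_gap > 0, noise_sd >= 0)
  structure(as.list(environment()), class = "huckel_params")
}

# pi-electron context of each atom: 0 (not in the pi system), 1
# (contributes one electron), or 2 (lone-pair donor)
pi_context <- function(mol) {
  hyb <- atom_hybridization(mol)
  at <- mol$atoms
  deg <- atom_degree(mol)
  ctx <- integer(nrow(at))
  for (i in seq_len(nrow(at))) {
    if (at$aromatic[i]) {
      el <- at$element[i]
      if (el %in% c("O", "S", "Se")) ctx[i] <- 2L
      else if (el == "N" && (at$h[i] > 0L || deg[i] >= 3L)) ctx[i] <- 2L
      else ctx[i] <- 1L
    } else if (hyb[i] %in% c("sp", "sp2")) {
      ctx[i] <- 1L
    }
  }
  ctx
}

#' Extract the conjugated pi system of a molecule
#'
#' Collects aromatic atoms and atoms carrying double/triple bonds, plus the
#' bonds among them (single bonds between two pi atoms are kept as
#' conjugating links, so biaryl and diene systems stay connected), and
#' builds the dimensionless Hamiltonian coefficient matrix.
#'
#' @param molecule A `ring_mol` or SMILES string.
#' @param params A [huckel_params()].
#' @return `NULL` if no atom is conjugated, else a list of class
#'   `pi_system`: `atom_indices`, `coef` (symmetric matrix with `h` diagonal
#'   and `k` off-diagonal entries), `n_pi_electrons`.
#' @export
extract_pi_system <- function(molecule, params = huckel_params()) {
  mol <- if (inherits(molecule, "ring_mol")) molecule else parse_smiles(molecule)
  ctx <- pi_context(mol)
  idx <- which(ctx > 0L)
  if (length(idx) == 0L) return(NULL)
  pos <- match(seq_len(nrow(mol$atoms)), idx)  # atom -> pi position
  np <- length(idx)
  coef <- matrix(0, np, np)
  for (i in seq_along(idx)) {
    el <- mol$atoms$element[idx[i]]
    hrow <- params$h_table[[el]]
    if (is.null(hrow)) {
      stop("no Coulomb correction (h) entry for element '", el, "'")
    }
    coef[i, i] <- unname(hrow[if (ctx[idx[i]] == 2L) "two" else "one"])
  }
  bd <- mol$bonds
  for (k in seq_len(nrow(bd))) {
    a <- pos[bd$a1[k]]; b <- pos[bd$a2[k]]
    if (is.na(a) || is.na(b)) next
    pair <- paste(sort(c(mol$atoms$element[bd$a1[k]],
                         mol$atoms$element[bd$a2[k]])), collapse = "-")
    kk <- if (pair %in% names(params$k_table)) params$k_table[[pair]]
          else params$k_default
    coef[a, b] <- kk; coef[b, a] <- kk
  }
  n_pi <- sum(ctx[idx])
  structure(list(atom_indices = idx, coef = coef,
                 n_pi_electrons = as.integer(n_pi)),
            class = "pi_system")
}

#' Solve the Hueckel secular problem
#'
#' @param pi A `pi_system` from [extract_pi_system()].
#' @param params A [huckel_params()] supplying `alpha` and `beta`.
#' @return Orbital energies in eV, ascending.
#' @export
huckel_solve <- function(pi, params = huckel_params()) {
  stopifnot(inherits(pi, "pi_system"))
  H <- diag(params$alpha, nrow(pi$coef)) + params$beta * pi$coef
  sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
}

#' Frontier orbitals and HOMO-LUMO gap
#'
#' Electrons fill the ascending spectrum in pairs; the HOMO is orbital
#' `n/2` (1-based) and the LUMO the next one. Degenerate frontier levels
#' are resolved by the ascending-index convention, which leaves the gap
#' unchanged.
#'
#' @param energies Ascending orbital energies (eV).
#' @param n_pi_electrons Even electron count, at most `2*length(energies)`.
#' @return A list with `eps_homo`, `eps_lumo`, `gap` (all eV).
#' @export
frontier_gap <- function(energies, n_pi_electrons) {
  if (n_pi_electrons %% 2L != 0L) {
    stop("odd pi-electron count (", n_pi_electrons, "): open-shell systems ",
         "are not supported")
  }
  if (n_pi_electrons <= 0L) stop("no pi electrons")
  n_occ <- n_pi_electrons / 2L
  if (n_occ >= length(energies)) {
    stop("all ", length(energies), " orbitals filled: no LUMO")
  }
  if (is.unsorted(energies)) stop("energies must be ascending")
  list(eps_homo = energies[n_occ],
       eps_lumo = energies[n_occ + 1L],
       gap = energies[n_occ + 1L] - energies[n_occ])
}

# sigma-only fallback: group contributions on the heavy-atom composition
sigma_properties <- function(mol, params) {
  counts <- element_counts(mol)
  het <- counts[setdiff(names(counts), "C")]
  gcorr <- sum(params$sigma_gap_corr[names(het)] * het, na.rm = TRUE)
  icorr <- sum(params$sigma_ip_corr[names(het)] * het, na.rm = TRUE)
  gap <- max(0.5, params$sigma_default_gap + gcorr)
  ip <- params$sigma_ip_base - params$sigma_ip_size * sum(counts) - icorr
  list(gap = gap, ip = ip, ea = ip - gap)
}

#' Synthetic electronic properties of one molecule
#'
#' If the molecule has a pi system, `gap`, `ip` and `ea` come from its
#' frontier Hueckel orbitals (Koopmans: IP = -eps_HOMO, EA = -eps_LUMO);
#' otherwise from the sigma group-contribution model in `params`. Redox
#' labels are always the planted linear maps of IP and EA plus
#' `N(0, noise_sd)` noise drawn from the current RNG state (seed the RNG,
#' or use [label_molecules()], for reproducibility).
#'
#' @param molecule A `ring_mol` or SMILES string.
#' @param params A [huckel_params()].
#' @return A list with `gap`, `ip`, `ea` (eV) and `eox`, `ered` (V).
#' @export
oracle_properties <- function(molecule, params = huckel_params()) {
  mol <- if (inherits(molecule, "ring_mol")) molecule else parse_smiles(molecule)
  pi <- extract_pi_system(mol, params)
  if (is.null(pi)) {
    p <- sigma_properties(mol, params)
  } else {
    en <- huckel_solve(pi, params)
    fr <- frontier_gap(en, pi$n_pi_electrons)
    p <- list(gap = fr$gap, ip = -fr$eps_homo, ea = -fr$eps_lumo)
  }
  noise <- if (params$noise_sd > 0) stats::rnorm(2, 0, params$noise_sd)
           else c(0, 0)
  p$eox <- params$ox_slope * p$ip + params$ox_intercept + noise[1]
  p$ered <- params$red_slope * p$ea + params$red_intercept + noise[2]
  p
}

#' Label a molecule table with oracle properties
#'
#' @param records Molecule records (needs `mol_id`, `smiles`).
#' @param params A [huckel_params()].
#' @param seed Optional integer seed making the label noise reproducible.
#' @return A property data frame with columns `mol_id`, `gap_eV`, `ip_eV`,
#'   `ea_eV`, `eox_V`, `ered_V`.
#' @export
label_molecules <- function(records, params = huckel_params(), seed = NULL) {
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
  }
  props <- lapply(records$smiles, oracle_properties, params = params)
  data.frame(
    mol_id = records$mol_id,
    gap_eV = vapply(props, `[[`, numeric(1), "gap"),
    ip_eV = vapply(props, `[[`, numeric(1), "ip"),
    ea_eV = vapply(props, `[[`, numeric(1), "ea"),
    eox_V = vapply(props, `[[`, numeric(1), "eox"),
    ered_V = vapply(props, `[[`, numeric(1), "ered"),
    stringsAsFactors = FALSE
  )
}
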