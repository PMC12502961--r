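# Thermodynamic-cycle electrochemistry.
#
# Vertical IP/EA come from gas-phase single-point energies of the neutral
# and ionized molecule at the neutral geometry; electrode potentials come
# from aqueous Gibbs free energy differences between charge states,
# referenced to the standard hydrogen electrode. Energies are stored per
# molecule in eV, so dividing the reaction free energy by n electrons maps
# eV directly to V (the Faraday division is the identity per electron in
# these units).

HARTREE_EV <- 27.211386

#' Per-molecule energies of the three charge states
#'
#' @param mol_id Identifier.
#' @param E_gas Named numeric vector of gas-phase energies at the neutral
#'   geometry; names among `"-1"`, `"0"`, `"+1"`.
#' @param G_aq Named numeric vector of aqueous Gibbs free energies, same
#'   naming.
#' @param units `"eV"` (default) or `"hartree"`; hartree input is converted
#'   at load with 27.211386 eV/hartree.
#' @return A list of class `gibbs_set` (energies in eV).
#' @export
gibbs_set <- function(mol_id, E_gas = NULL, G_aq = NULL, units = c("eV", "hartree")) {
  units <- match.arg(units)
  conv <- if (units == "hartree") HARTREE_EV else 1
  norm <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.null(names(x)) || !all(names(x) %in% c("-1", "0", "+1"))) {
      stop("energies must be named by charge state: \"-1\", \"0\", \"+1\"")
    }
    if (any(!is.finite(x))) stop("non-finite energy for ", mol_id)
    x * conv
  }
  structure(list(mol_id = mol_id, E_gas = norm(E_gas), G_aq = norm(G_aq)),
            class = "gibbs_set")
}

need_charge <- function(x, charges, what) {
  if (is.null(x) || !all(charges %in% names(x))) {
    stop("missing ", what, " charge state(s): ",
         paste(setdiff(charges, names(x)), collapse = ", "))
  }
}

#' Electrochemistry configuration
#'
#' @param n_electrons Electrons transferred (1 for all systems here).
#' @param E_ref Reference electrode potential in V; 4.28 V is the absolute
#'   potential of the standard hydrogen electrode.
#' @export
electro_config <- function(n_electrons = 1L, E_ref = 4.28) {
  stopifnot(n_electrons >= 1L)
  structure(list(n_electrons = as.integer(n_electrons), E_ref = E_ref),
            class = "electro_config")
}

#' Vertical ionization potential
#'
#' `IP = E_gas(+1) - E_gas(0)` at the fixed neutral geometry.
#'
#' @param gibbs A [gibbs_set()].
#' @return IP in eV.
#' @export
vertical_ip <- function(gibbs) {
  need_charge(gibbs$E_gas, c("0", "+1"), "gas-phase")
  unname(gibbs$E_gas[["+1"]] - gibbs$E_gas[["0"]])
}

#' Vertical electron affinity
#'
#' `EA = E_gas(0) - E_gas(-1)`: positive when the anion is bound.
#'
#' @param gibbs A [gibbs_set()].
#' @return EA in eV.
#' @export
vertical_ea <- function(gibbs) {
  need_charge(gibbs$E_gas, c("0", "-1"), "gas-phase")
  unname(gibbs$E_gas[["0"]] - gibbs$E_gas[["-1"]])
}

#' Oxidation potential from the thermodynamic cycle
#'
#' `E_ox = [G_aq(+1) - G_aq(0)] / n - E_ref`, in V vs the reference
#' electrode.
#'
#' @param gibbs A [gibbs_set()].
#' @param cfg An [electro_config()].
#' @return E_ox in V.
#' @export
oxidation_potential <- function(gibbs, cfg = electro_config()) {
  need_charge(gibbs$G_aq, c("0", "+1"), "aqueous")
  unname((gibbs$G_aq[["+1"]] - gibbs$G_aq[["0"]]) / cfg$n_electrons -
           cfg$E_ref)
}

#' Reduction potential from the thermodynamic cycle
#'
#' `E_red = [G_aq(0) - G_aq(-1)] / n - E_ref`: a more stable anion gives a
#' higher (less negative) reduction potential, i.e. a better electron
#' acceptor.
#'
#' @param gibbs A [gibbs_set()].
#' @param cfg An [electro_config()].
#' @return E_red in V.
#' @export
reduction_potential <- function(gibbs, cfg = electro_config()) {
  need_charge(gibbs$G_aq, c("0", "-1"), "aqueous")
  unname((gibbs$G_aq[["0"]] - gibbs$G_aq[["-1"]]) / cfg$n_electrons -
           cfg$E_ref)
}

#' Read a Gibbs free energy table
#'
#' CSV columns: `id, charge, phase, energy, units` with `charge` in
#' \{-1, 0, 1\}, `phase` in \{gas, aq\} and `units` in \{eV, hartree\}.
#'
#' @param path CSV path.
#' @return Named list of [gibbs_set()] objects, one per id.
#' @export
read_gibbs_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "charge", "phase", "energy", "units")
  if (!all(need %in% names(df))) {
    stop("missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  out <- list()
  for (id in unique(df$id)) {
    sub <- df[df$id == id, ]
    mk <- function(phase) {
      ss <- sub[sub$phase == phase, ]
      if (nrow(ss) == 0L) return(NULL)
      conv <- ifelse(ss$units == "hartree", HARTREE_EV, 1)
      key <- ifelse(ss$charge > 0, "+1", as.character(ss$charge))
      stats::setNames(ss$energy * conv, key)
    }
    out[[id]] <- gibbs_set(id, E_gas = mk("gas"), G_aq = mk("aq"))
  }
  out
}

#' Ordinary least-squares fit of a property pair
#'
#' @param x,y Paired numeric vectors (at least 3 finite pairs).
#' @return A list with `slope`, `intercept`, `r_squared` (squared Pearson
#'   correlation) and `n`.
#' @export
linear_correlation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 paired finite values")
  vx <- stats::var(x)
  if (vx == 0) stop("zero variance in x")
  slope <- stats::cov(x, y) / vx
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (stats::var(y) == 0) 1 else stats::cor(x, y)^2
  list(slope = slope, intercept = intercept, r_squared = r2, n = length(x))
}
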