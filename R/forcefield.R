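#' Interaction parameters of the coarse-grained lipid model
#'
#' Bundles every constant of the bead-spring amphiphile force field: the FENE
#' bond potential, the harmonic bond-angle potential, and the shifted
#' soft-core pair potential acting between non-bonded beads.  The defaults
#' reproduce the canonical parameter set of the single-tail Lenz--Schmid
#' lipid: `nu_fene = 100`, `r0 = 0.7`, `dr_m = 0.2`, `nu_ba = 4.7`, with
#' pair interactions tail-tail (epsilon 1, sigma 1, cutoff 2 sigma),
#' head-tail (sigma 1.05, cutoff 1 sigma) and head-head / solvent-head /
#' solvent-tail (sigma 1.1, cutoff 1 sigma).  Solvent beads are phantom:
#' the solvent-solvent pair is inactive.
#'
#' All quantities are in reduced units: energies in epsilon, lengths in
#' sigma_LJ of the tail bead, k_B = 1.
#'
#' @param nu_fene FENE spring strength (epsilon / sigma_LJ^2).
#' @param r0 Optimal bond length (sigma_LJ).
#' @param dr_m Maximal bond stretching distance (sigma_LJ).
#' @param nu_ba Bond-angle strength (epsilon); 0 disables the angle term.
#' @param pair_table Data frame with columns `kind1`, `kind2`, `epsilon`,
#'   `sigma`, `rc_mult` (cutoff in multiples of that pair's sigma) and
#'   `active`; see [default_pair_table()].
#' @param exclude_bonded If `TRUE` (default), directly bonded beads do not
#'   interact through the soft-core potential (the FENE bond replaces it);
#'   second and further neighbours along a chain do interact.
#' @return An object of class `ff_params`.
#' @export
#' @examples
#' ff <- forcefield_params()
#' fene_energy(0.8, ff)
forcefield_params <- function(nu_fene = 100, r0 = 0.7, dr_m = 0.2,
                              nu_ba = 4.7, pair_table = default_pair_table(),
                              exclude_bonded = TRUE) {
  stopifnot(nu_fene > 0, r0 > 0, dr_m > 0, nu_ba >= 0)
  kinds <- c("head", "tail", "solvent")
  req <- c("kind1", "kind2", "epsilon", "sigma", "rc_mult", "active")
  if (!all(req %in% names(pair_table)))
    stop("pair_table must have columns: ", paste(req, collapse = ", "))
  if (!all(pair_table$kind1 %in% kinds) || !all(pair_table$kind2 %in% kinds))
    stop("pair_table kinds must be head/tail/solvent")
  eps <- sig <- rcm <- matrix(0, 3, 3, dimnames = list(kinds, kinds))
  act <- matrix(0L, 3, 3, dimnames = list(kinds, kinds))
  for (r in seq_len(nrow(pair_table))) {
    a <- pair_table$kind1[r]; b <- pair_table$kind2[r]
    eps[a, b] <- eps[b, a] <- pair_table$epsilon[r]
    sig[a, b] <- sig[b, a] <- pair_table$sigma[r]
    rcm[a, b] <- rcm[b, a] <- pair_table$rc_mult[r]
    act[a, b] <- act[b, a] <- as.integer(pair_table$active[r])
  }
  if (act["solvent", "solvent"] != 0L)
    stop("the solvent-solvent pair must be inactive (phantom solvent)")
  structure(list(nu_fene = nu_fene, r0 = r0, dr_m = dr_m, nu_ba = nu_ba,
                 epsilon = eps, sigma = sig, rc_mult = rcm, active = act,
                 pair_table = pair_table, exclude_bonded = exclude_bonded),
            class = "ff_params")
}

#' Default pair-interaction table of the model
#'
#' One row per unordered bead-kind pair.  `rc_mult` is the cutoff in
#' multiples of that pair's `sigma`; pairs with `rc_mult = 1` are purely
#' repulsive because the minimum of the Lennard-Jones core sits exactly at
#' the cutoff.  The solvent-solvent row is inactive: solvent beads are
#' phantom particles that exert pressure on the membrane but carry no
#' solvent-solvent structure.
#'
#' @return A data frame usable as the `pair_table` of [forcefield_params()].
#' @export
default_pair_table <- function() {
  data.frame(
    kind1   = c("tail", "head", "head", "solvent", "solvent", "solvent"),
    kind2   = c("tail", "tail", "head", "head", "tail", "solvent"),
    epsilon = c(1, 1, 1, 1, 1, 0),
    sigma   = c(1, 1.05, 1.1, 1.1, 1.1, 1),
    rc_mult = c(2, 1, 1, 1, 1, 0),
    active  = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

#' FENE bond-stretching energy
#'
#' Finitely extensible nonlinear elastic bond:
#' `V(r) = -(nu_fene/2) * dr_m^2 * log(1 - ((r - r0)/dr_m)^2)`.
#' The energy is zero at the optimal length `r0`, symmetric about it, and
#' diverges as `|r - r0|` approaches the maximal stretching distance `dr_m`.
#'
#' @param r Bond length(s), sigma_LJ.
#' @param params An [forcefield_params()] object.
#' @return Energy in epsilon, vectorised over `r`.
#' @export
fene_energy <- function(r, params = forcefield_params()) {
  x <- (r - params$r0) / params$dr_m
  if (any(abs(x) >= 1))
    stop("bond length outside FENE domain: |r - r0| must be < dr_m (broken bond)")
  -0.5 * params$nu_fene * params$dr_m^2 * log(1 - x^2)
}

#' Harmonic bond-angle energy
#'
#' `V(theta) = nu_ba * (1 - cos(theta))` where `theta` is the angle between
#' successive bond vectors of three adjacent beads; `theta = 0` means a
#' straight chain, so the term penalises chain bending.  The cosine is
#' clamped to `[-1, 1]` against round-off.
#'
#' @param theta Angle(s) in radians, in `[0, pi]`.
#' @param params An [forcefield_params()] object.
#' @return Energy in epsilon, vectorised over `theta`.
#' @export
bond_angle_energy <- function(theta, params = forcefield_params()) {
  params$nu_ba * (1 - pmin(1, pmax(-1, cos(theta))))
}

#' Shifted soft-core pair energy
#'
#' `V(r) = (V_LJ(r) - V_LJ(r_c)) * theta(r_c - r)` with
#' `V_LJ(r) = epsilon * ((sigma/r)^12 - 2 * (sigma/r)^6)`, so the potential
#' is continuous at the cutoff and exactly zero beyond it (the Heaviside
#' convention is `theta(0) = 0`).  For pairs whose cutoff equals sigma the
#' attractive well is cut away and the interaction is purely repulsive.
#' Inactive pairs (solvent-solvent) return 0 by contract.
#'
#' @param r Distance(s), sigma_LJ; must be positive.
#' @param kinds Character vector of length 2, e.g. `c("tail", "tail")`.
#' @param params An [forcefield_params()] object.
#' @return Energy in epsilon, vectorised over `r`.
#' @export
soft_core_energy <- function(r, kinds, params = forcefield_params()) {
  stopifnot(length(kinds) == 2, all(r > 0))
  a <- kinds[1]; b <- kinds[2]
  if (!params$active[a, b]) return(rep(0, length(r)))
  eps <- params$epsilon[a, b]; sig <- params$sigma[a, b]
  rc <- params$rc_mult[a, b] * sig
  vlj <- function(rr) eps * ((sig / rr)^12 - 2 * (sig / rr)^6)
  ifelse(r >= rc, 0, vlj(r) - vlj(rc))
}

# ---- internal plumbing --------------------------------------------------

# force-field list as consumed by the C++ engine; bond_style 0 = FENE,
# 1 = harmonic (used by the toy spring networks)
ff_to_cpp <- function(params, config = NULL) {
  style <- 0L; hk <- 0; hr0 <- 0
  if (!is.null(config) && identical(config$bond_style, "harmonic")) {
    style <- 1L
    hk <- config$bond_params$k
    hr0 <- config$bond_params$r0
  }
  list(bond_style = style, nu_fene = params$nu_fene, r0 = params$r0,
       dr_m = params$dr_m, harmonic_k = hk, harmonic_r0 = hr0,
       nu_ba = if (!is.null(config) && !config$use_angles) 0 else params$nu_ba,
       epsilon = params$epsilon, sigma = params$sigma,
       rc_mult = params$rc_mult, active = params$active,
       exclude_bonded = isTRUE(params$exclude_bonded))
}

#' Total potential energy of a configuration
#'
#' Sums the FENE (or harmonic) bond energies, bond-angle energies and
#' soft-core pair energies of a configuration under the minimum-image
#' convention on all three periodic axes.  Directly bonded beads are
#' excluded from the pair sum (the bond potential replaces it); all other
#' intra- and intermolecular pairs interact.
#'
#' @param config A [mem_config()] object.
#' @param params An [forcefield_params()] object.
#' @return Total energy (epsilon) with attribute `"components"` holding the
#'   bond / angle / pair / external-well breakdown.
#' @export
total_energy <- function(config, params = forcefield_params()) {
  cc <- config_to_cpp(config)
  e <- cpp_total_energy(cc$positions, cc$kind, cc$box, cc$bonds, cc$angles,
                        ff_to_cpp(params, config), cc$well)
  structure(e$total, components = c(bond = e$bond, angle = e$angle,
                                    pair = e$pair, well = e$well))
}

#' Energy change of a proposed Monte Carlo move
#'
#' For a single-bead displacement the change is computed incrementally from
#' the bead's local environment (its bonds, angle triples, pair neighbours
#' and external well); for a box-axis rescale it is the difference of two
#' full energy evaluations.  Both agree with
#' `total_energy(after) - total_energy(before)` to accumulation tolerance.
#'
#' @param config A [mem_config()] object.
#' @param move A list: either `list(type = "displace", bead = i, new = c(x, y, z))`
#'   or `list(type = "rescale", axis = "x"|"y"|"z", factor = s)`.
#' @param params An [forcefield_params()] object.
#' @return The energy difference in epsilon.
#' @export
delta_energy <- function(config, move, params = forcefield_params()) {
  cc <- config_to_cpp(config)
  ffc <- ff_to_cpp(params, config)
  if (identical(move$type, "displace")) {
    cpp_displace_delta(cc$positions, cc$kind, cc$box, cc$bonds, cc$angles,
                       ffc, cc$well, as.integer(move$bead),
                       as.numeric(move$new))
  } else if (identical(move$type, "rescale")) {
    ax <- match(move$axis, c("x", "y", "z"))
    if (is.na(ax)) stop("rescale axis must be one of x, y, z")
    e0 <- total_energy(config, params)
    cfg2 <- config
    cfg2$positions[, ax] <- cfg2$positions[, ax] * move$factor
    cfg2$box[ax] <- cfg2$box[ax] * move$factor
    e1 <- total_energy(cfg2, params)
    as.numeric(e1) - as.numeric(e0)
  } else {
    stop("move$type must be 'displace' or 'rescale'")
  }
}
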