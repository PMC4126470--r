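#' Thermodynamic phase point
#'
#' Preset (pressure, temperature) state points of the model's gel, fluid and
#' interdigitated bilayer phases, in reduced units (P in epsilon/sigma_LJ^3,
#' T in epsilon/k_B).  `T_anneal` is the slightly raised temperature used to
#' accelerate re-equilibration right after the uniaxial box rescale of the
#' Poisson protocol.  `area_per_lipid` and `thickness` are the equilibrium
#' reference values of each phase, used to seed initial constructions.
#'
#' @param name One of `"gel"`, `"fluid"`, `"interdigitated"`, or `"custom"`.
#' @param P,T,T_anneal Override the preset values (required for `"custom"`).
#' @return An object of class `phase_point`.
#' @export
#' @examples
#' phase_point("fluid")        # P = 1, T = 1.3
#' phase_point("custom", P = 0, T = 0.2)
phase_point <- function(name = c("fluid", "gel", "interdigitated", "custom"),
                        P = NULL, T = NULL, T_anneal = NULL) {
  name <- match.arg(name)
  presets <- list(
    gel            = list(P = 2,   T = 1.08, T_anneal = 1.2,
                          area_per_lipid = 0.96, thickness = 7.64),
    fluid          = list(P = 1,   T = 1.3,  T_anneal = 1.4,
                          area_per_lipid = 1.68, thickness = 5.48),
    interdigitated = list(P = 0.5, T = 1.16, T_anneal = 1.3,
                          area_per_lipid = 1.8,  thickness = 4.8))
  if (name == "custom") {
    if (is.null(P) || is.null(T)) stop("custom phase point needs P and T")
    p <- list(P = P, T = T, T_anneal = if (is.null(T_anneal)) T else T_anneal,
              area_per_lipid = NA_real_, thickness = NA_real_)
  } else {
    p <- presets[[name]]
    if (!is.null(P)) p$P <- P
    if (!is.null(T)) p$T <- T
    if (!is.null(T_anneal)) p$T_anneal <- T_anneal
  }
  structure(c(list(name = name), p), class = "phase_point")
}

#' @export
print.phase_point <- function(x, ...) {
  cat(sprintf("<phase_point> %s: P = %g, T = %g (anneal T = %g)\n",
              x$name, x$P, x$T, x$T_anneal))
  invisible(x)
}

#' Build an initial bilayer plus phantom solvent
#'
#' Places two leaflets of `nx * ny` straight-chain lipids each on a square
#' lattice (heads outward, chains along z, all bonds at the optimal FENE
#' length `r0`, all angles zero) and fills the remaining volume with
#' phantom solvent beads at a target number density.  For the
#' interdigitated phase the two leaflets are offset laterally by half a
#' lattice vector and overlapped along z so that opposing tails
#' interpenetrate.  The construction guarantees that no active pair sits
#' closer than 0.8 of its pair sigma.
#'
#' @param nx,ny Lipids per row / column of each leaflet (each >= 2).
#' @param phase A [phase_point()]; its reference area per lipid seeds the
#'   lattice spacing unless overridden.
#' @param area_per_lipid_init Initial area per lipid (sigma_LJ^2); default
#'   is the phase preset's equilibrium value, which shortens equilibration.
#' @param solvent_density Phantom-solvent number density (beads/sigma_LJ^3);
#'   default `P / T` of the phase, the ideal-gas density at that state
#'   point, so the initial box is close to pressure balance.
#' @param solvent_pad Height of the solvent slab above and below the
#'   membrane (sigma_LJ).
#' @param seed Integer seed for the solvent placement.
#' @param ff An [forcefield_params()] object (for `r0` and overlap checks).
#' @return A [mem_config()] containing `2 * nx * ny` lipids and the solvent.
#' @export
build_bilayer <- function(nx, ny, phase = phase_point("fluid"),
                          area_per_lipid_init = NULL, solvent_density = NULL,
                          solvent_pad = 6, seed = 1,
                          ff = forcefield_params()) {
  stopifnot(nx >= 2, ny >= 2)
  A <- if (is.null(area_per_lipid_init)) phase$area_per_lipid else area_per_lipid_init
  if (!is.finite(A) || A <= 0)
    stop("area_per_lipid_init must be given for custom phase points")
  rho_s <- if (is.null(solvent_density)) phase$P / phase$T else solvent_density
  a <- sqrt(A)
  Lx <- nx * a; Ly <- ny * a
  r0 <- ff$r0
  inter <- identical(phase$name, "interdigitated")

  # one straight 7-bead chain: head first, tails below (direction dir = +-1),
  # head at z_head, beads spaced r0
  chain_z <- function(z_head, dir) z_head - dir * r0 * (0:6)

  z_gap <- 0.45                      # half-gap between opposing terminal tails
  z_head_off <- z_gap + 6 * r0       # head height above the midplane

  pos <- list(); kinds <- character(0); mols <- list(); bead <- 0
  lat <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1))
  add_leaflet <- function(dir, dx, dy, z_head) {
    for (r in seq_len(nrow(lat))) {
      x <- (lat$i[r] + 0.5) * a + dx
      y <- (lat$j[r] + 0.5) * a + dy
      z <- chain_z(z_head, dir)
      pos[[length(pos) + 1]] <<- cbind(rep(x, 7), rep(y, 7), z)
      kinds <<- c(kinds, c("head", rep("tail", 6)))
      mols[[length(mols) + 1]] <<- bead + 1:7
      bead <<- bead + 7
    }
  }
  if (!inter) {
    add_leaflet(+1, 0, 0, z_head_off)   # upper leaflet, head on top
    add_leaflet(-1, 0, 0, -z_head_off)  # lower leaflet, mirrored
    z_top <- z_head_off
  } else {
    # chains span [-(6 r0 - ov/2), ov/2 + ...]: upper head up at z_u,
    # lower leaflet flipped, laterally offset by half a lattice vector
    ov <- 4 * r0
    z_u <- 6 * r0 - ov / 2
    add_leaflet(+1, 0, 0, z_u)
    add_leaflet(-1, a / 2, a / 2, -z_u)
    z_top <- z_u
  }

  # box: membrane centred, solvent slabs of height solvent_pad on both sides
  clear <- 1.0                          # z clearance between heads and solvent
  Lz <- 2 * (z_top + clear + solvent_pad)
  n_solv <- round(rho_s * Lx * Ly * 2 * solvent_pad)
  if (n_solv > 0) {
    set.seed(as.integer(seed))
    sx <- runif(n_solv, 0, Lx)
    sy <- runif(n_solv, 0, Ly)
    half <- runif(n_solv) < 0.5
    sz <- runif(n_solv, z_top + clear, Lz / 2 - 0.05)
    sz[half] <- -sz[half]
    pos[[length(pos) + 1]] <- cbind(sx, sy, sz)
    kinds <- c(kinds, rep("solvent", n_solv))
    for (s in seq_len(n_solv)) mols[[length(mols) + 1]] <- bead + s
    bead <- bead + n_solv
  }

  P <- do.call(rbind, pos)
  P[, 3] <- P[, 3] + Lz / 2             # centre membrane at z = Lz/2
  cfg <- mem_config(P, kinds, mols, box = c(Lx, Ly, Lz))

  cc <- config_to_cpp(cfg)
  ratio <- cpp_min_pair_ratio(cc$positions, cc$kind, cc$box, cc$bonds,
                              ff_to_cpp(ff, cfg))
  if (is.finite(ratio) && ratio < 0.8)
    stop(sprintf(paste0("packing infeasible: closest active pair at ",
                        "%.3f of its sigma (< 0.8); reduce density"), ratio))
  cfg
}

#' Membrane descriptors of a bilayer configuration
#'
#' Computes the standard structural observables of a bilayer snapshot:
#' \describe{
#'   \item{chain_length_mean}{mean head-to-terminal-tail-bead distance
#'     (sigma_LJ).}
#'   \item{thickness}{distance between the mean head-bead heights of the
#'     two leaflets (sigma_LJ).}
#'   \item{area_per_lipid}{lateral box area divided by lipids per leaflet
#'     (sigma_LJ^2).}
#'   \item{order_parameter}{S_z, the second-Legendre average
#'     `mean((3 cos^2 a - 1) / 2)` over all tail-tail bonds, `a` being the
#'     bond angle to the z axis; 1 for chains aligned with z, 0 isotropic.}
#' }
#' Leaflets are identified at call time from the sign of the head height
#' relative to the instantaneous bilayer midplane (the mean z of all lipid
#' beads), so flip-flopped lipids are reassigned at every measurement.
#'
#' @param config A [mem_config()] holding a bilayer (plus optional solvent).
#' @return An object of class `membrane_descriptors` (a named list).
#' @export
membrane_descriptors <- function(config) {
  lip <- lipid_molecules(config)
  if (length(lip) < 2) stop("configuration holds no bilayer (need >= 2 lipids)")
  pos <- config$positions
  lip_beads <- unlist(lip)
  mid <- mean(pos[lip_beads, 3])
  heads <- vapply(lip, `[`, integer(1), 1)
  hz <- pos[heads, 3]
  upper <- hz > mid
  if (!any(upper) || all(upper))
    stop("leaflet identification failed: head heights are not bimodal")
  d <- abs(mean(hz[upper]) - mean(hz[!upper]))
  if (d < 1) stop("leaflet identification failed: leaflets are not separated")

  # head-to-terminal-tail distance per lipid (minimum image)
  tails_end <- vapply(lip, `[`, integer(1), 7)
  dvec <- pos[heads, , drop = FALSE] - pos[tails_end, , drop = FALSE]
  for (a in 1:3) {
    L <- config$box[a]
    dvec[, a] <- dvec[, a] - L * round(dvec[, a] / L)
  }
  lbar <- mean(sqrt(rowSums(dvec^2)))

  A <- config$box[1] * config$box[2] / (length(lip) / 2)

  # S_z over tail-tail bonds (beads 2..7 of each chain -> 5 bonds per lipid)
  b1 <- unlist(lapply(lip, function(m) m[2:6]))
  b2 <- unlist(lapply(lip, function(m) m[3:7]))
  bv <- pos[b1, , drop = FALSE] - pos[b2, , drop = FALSE]
  for (a in 1:3) {
    L <- config$box[a]
    bv[, a] <- bv[, a] - L * round(bv[, a] / L)
  }
  c2 <- bv[, 3]^2 / rowSums(bv^2)
  sz <- mean((3 * c2 - 1) / 2)

  structure(list(chain_length_mean = lbar, thickness = d,
                 area_per_lipid = A, order_parameter = sz,
                 n_lipids = length(lip)),
            class = "membrane_descriptors")
}

#' @export
print.membrane_descriptors <- function(x, ...) {
  cat(sprintf(paste0("<membrane_descriptors> l_bar = %.3f, d = %.3f, ",
                     "A = %.3f, S_z = %.3f (%d lipids)\n"),
              x$chain_length_mean, x$thickness, x$area_per_lipid,
              x$order_parameter, x$n_lipids))
  invisible(x)
}
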