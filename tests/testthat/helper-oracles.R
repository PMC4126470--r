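# Independent oracles written in plain R, deliberately naive: brute-force
# double loops, no cell lists, no incremental updates.  They exist to check
# the compiled engine against a second, simpler path.

min_image <- function(d, L) d - L * round(d / L)

pair_dist <- function(pos, box, i, j) {
  d <- pos[i, ] - pos[j, ]
  for (a in 1:3) d[a] <- min_image(d[a], box[a])
  sqrt(sum(d^2))
}

# total energy by brute force over all bonds, chain triples and pairs
brute_energy <- function(config, ff = forcefield_params()) {
  pos <- config$positions
  box <- config$box
  e <- 0
  for (b in seq_len(nrow(config$bonds))) {
    r <- pair_dist(pos, box, config$bonds[b, 1], config$bonds[b, 2])
    e <- e + if (config$bond_style == "fene") fene_energy(r, ff) else
      0.5 * config$bond_params$k * (r - config$bond_params$r0)^2
  }
  if (config$use_angles) {
    for (m in config$molecules) {
      if (length(m) < 3) next
      for (t in seq_len(length(m) - 2)) {
        i <- m[t]; j <- m[t + 1]; k <- m[t + 2]
        u <- pos[j, ] - pos[i, ]; v <- pos[k, ] - pos[j, ]
        for (a in 1:3) {
          u[a] <- min_image(u[a], box[a]); v[a] <- min_image(v[a], box[a])
        }
        ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
        e <- e + bond_angle_energy(acos(max(-1, min(1, ct))), ff)
      }
    }
  }
  bonded <- paste(pmin(config$bonds[, 1], config$bonds[, 2]),
                  pmax(config$bonds[, 1], config$bonds[, 2]))
  n <- nrow(pos)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (paste(i, j) %in% bonded) next
      r <- pair_dist(pos, box, i, j)
      e <- e + soft_core_energy(r, c(config$kinds[i], config$kinds[j]), ff)
    }
  }
  if (!is.null(config$well)) {
    for (i in seq_len(n)) {
      d <- pos[i, ] - config$well$center
      for (a in 1:3) d[a] <- min_image(d[a], box[a])
      e <- e + 0.5 * config$well$k * sum(d^2)
    }
  }
  e
}

# harmonic spring-network energy under an affine in-plane deformation;
# independent of the engine (used as the static oracle for Poisson's ratio)
spring_energy_scaled <- function(net, sx = 1, sy = 1) {
  pos <- net$positions
  pos[, 1] <- pos[, 1] * sx
  pos[, 2] <- pos[, 2] * sy
  box <- net$box * c(sx, sy, 1)
  k <- net$bond_params$k; r0 <- net$bond_params$r0
  d <- pos[net$bonds[, 1], , drop = FALSE] - pos[net$bonds[, 2], , drop = FALSE]
  for (a in 1:3) d[, a] <- d[, a] - box[a] * round(d[, a] / box[a])
  r <- sqrt(rowSums(d^2))
  sum(0.5 * k * (r - r0)^2)
}

# static Poisson's ratio of a spring network: impose strain eta along y,
# minimise the energy over the transverse scale
static_poisson <- function(net, eta) {
  o <- stats::optimize(function(sx) spring_energy_scaled(net, sx, 1 + eta),
                       c(0.8, 1.05), tol = 1e-10)
  -(o$minimum - 1) / eta
}

# small perturbed bilayer patch without solvent, for energy-delta tests
small_bilayer <- function(nx = 2, ny = 2, jitter = 0.03, seed = 42) {
  cfg <- build_bilayer(nx, ny, phase_point("fluid"), solvent_density = 0,
                       solvent_pad = 2, seed = seed)
  set.seed(seed)
  cfg$positions <- cfg$positions +
    matrix(runif(length(cfg$positions), -jitter, jitter),
           nrow(cfg$positions), 3)
  cfg
}

# synthetic bilayer whose midplane follows A*cos(2*pi*x/Lx): one lipid per
# grid cell per leaflet, heads at +-offset from the local midplane
corrugated_bilayer <- function(n = 16, L = 32, amp = 0.8, offset = 2.8) {
  a <- L / n
  pos <- list(); mols <- list(); kinds <- character(0); bead <- 0
  for (leaf in c(1, -1)) {
    for (j in 0:(n - 1)) {
      for (i in 0:(n - 1)) {
        x <- (i + 0.5) * a; y <- (j + 0.5) * a
        zh <- amp * cos(2 * pi * x / L) + leaf * offset
        z <- zh - leaf * 0.7 * (0:6)
        pos[[length(pos) + 1]] <- cbind(rep(x, 7), rep(y, 7), z + L / 2)
        kinds <- c(kinds, c("head", rep("tail", 6)))
        mols[[length(mols) + 1]] <- bead + 1:7
        bead <- bead + 7
      }
    }
  }
  mem_config(do.call(rbind, pos), kinds, mols, box = c(L, L, L))
}
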