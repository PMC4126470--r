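#' Rescale a configuration along one lateral axis
#'
#' Multiplies all coordinates and the box length along `axis` by
#' `(1 + eta)`, the elementary strain step of the Poisson-ratio protocol.
#' Rescaling along z is forbidden: there the stretch would act between
#' bonded beads inside each lipid and break FENE bonds instead of opening
#' free volume between molecules.  Before applying the strain the FENE
#' domain of every bond is checked; on violation the error reports the
#' largest admissible strain for this configuration.
#'
#' @param config A [mem_config()] object.
#' @param eta Axial strain (dimensionless); may be negative.
#' @param axis `"x"` or `"y"`.
#' @return The rescaled configuration.
#' @export
rescale_axial <- function(config, eta, axis = c("y", "x")) {
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  fac <- 1 + eta
  if (fac <= 0) stop("strain must satisfy 1 + eta > 0")
  if (config$bond_style == "fene") {
    rng <- admissible_strain(config, axis)
    if (eta < rng[1] || eta > rng[2])
      stop(sprintf(paste0("strain eta = %g breaks a FENE bond; admissible ",
                          "range for this configuration: [%.4f, %.4f]"),
                   eta, rng[1], rng[2]))
  }
  config$positions[, ax] <- config$positions[, ax] * fac
  config$box[ax] <- config$box[ax] * fac
  config
}

#' Admissible strain range of a configuration
#'
#' Largest uniaxial strain interval `[eta_min, eta_max]` along `axis` for
#' which every FENE bond stays inside its domain
#' `|r - r0| < dr_m` after the affine rescale.
#'
#' @param config A [mem_config()] object with FENE bonds.
#' @param axis `"x"` or `"y"`.
#' @param ff An [forcefield_params()] object.
#' @return Numeric length-2 vector `c(eta_min, eta_max)`.
#' @export
admissible_strain <- function(config, axis = c("y", "x"),
                              ff = forcefield_params()) {
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  b <- config$bonds
  if (nrow(b) == 0) return(c(-Inf, Inf))
  d <- config$positions[b[, 1], , drop = FALSE] -
    config$positions[b[, 2], , drop = FALSE]
  for (a in 1:3) {
    L <- config$box[a]
    d[, a] <- d[, a] - L * round(d[, a] / L)
  }
  da2 <- d[, ax]^2
  perp2 <- rowSums(d^2) - da2
  rmax <- ff$r0 + ff$dr_m
  rmin <- ff$r0 - ff$dr_m
  # bond length under scale s: r(s)^2 = perp2 + s^2 da2, monotone in s
  smax2 <- ifelse(da2 > 1e-300, (rmax^2 - perp2) / da2, Inf)
  smax <- sqrt(pmax(smax2, 0))
  # compression limit: only binds if the bond can get shorter than rmin
  smin2 <- ifelse(da2 > 1e-300 & perp2 < rmin^2, (rmin^2 - perp2) / da2, 0)
  smin <- sqrt(pmax(smin2, 0))
  tol <- 1e-9
  c(max(smin) - 1 + tol, min(smax) - 1 - tol)
}

#' Measure the Poisson's ratio by uniaxial box rescaling
#'
#' The central protocol: starting from a configuration pre-equilibrated at
#' the phase point, (1) a short baseline run establishes the pre-strain
#' equilibrium box lengths `L_i(0)` (mean over its last quarter); (2) the
#' box and all inter-particle distances along `axis` are rescaled so that
#' the strained length is exactly `(1 + eta) * L_axis(0)`; (3) the system
#' re-equilibrates with the strained axis held fixed, first for
#' `anneal_sweeps` at the phase's bumped temperature `T_anneal` (extra
#' mobility right after the strain), then at the phase temperature; (4) the
#' transverse relaxation traces `-(L_i(t) - L_i(0)) / (eta * L_i(0))` are
#' recorded for every free axis i and averaged over the plateau
#' `[burn_in, end]`, giving `nu_ij` with a block-averaged standard error.
#' A linear slope check over the averaging window flags non-converged runs.
#'
#' For bilayers the box height is solvent-dominated, so alongside the
#' box-length estimate of `nu_z*` a membrane-thickness-based trace is
#' recorded when `descriptor_every > 0`.
#'
#' With `eta = 0` (zero-strain control) the traces are the raw relative
#' length changes `-(L_i(t) - L_i(0)) / L_i(0)`, whose plateau average must
#' be consistent with zero.
#'
#' @param config Pre-equilibrated [mem_config()].
#' @param phase A [phase_point()].
#' @param eta Axial strain; default 0.05.
#' @param axis Strained axis, `"x"` or `"y"` (z is forbidden).
#' @param relax_sweeps Relaxation sweeps after the strain.
#' @param anneal_sweeps Sweeps at `T_anneal` right after the strain.
#' @param burn_in Sweeps discarded before plateau averaging.
#' @param baseline_sweeps Pre-strain sweeps used to fix `L_i(0)`.
#' @param settings An [mc_settings()]; its `seed` governs the whole
#'   protocol, its `fixed_axes` are augmented with the strained axis
#'   during relaxation.
#' @param ff An [forcefield_params()] object.
#' @param descriptor_every Stride for the thickness trace (0 = off; only
#'   meaningful for bilayer configurations).
#' @return An object of class `poisson_result`: `eta`, `axis`, `L0`,
#'   `traces` (data frame), `plateau_window`, `nu` (data frame with one row
#'   per response axis: estimate, stderr, converged flag), and optionally
#'   `nu_thickness`.
#' @export
measure_poisson <- function(config, phase, eta = 0.05, axis = c("y", "x"),
                            relax_sweeps = 15000, anneal_sweeps = 400,
                            burn_in = 5000, baseline_sweeps = 4000,
                            settings = mc_settings(sweeps = 0, seed = 1),
                            ff = forcefield_params(), descriptor_every = 0) {
  axis <- match.arg(axis)
  stopifnot(relax_sweeps > burn_in + 100, anneal_sweeps >= 0,
            anneal_sweeps <= relax_sweeps)
  if (!is.null(settings$seed)) set.seed(as.integer(settings$seed))
  settings$seed <- NULL
  settings$adapt_acceptance <- FALSE    # adaptation would break detailed balance
  axes <- c("x", "y", "z")
  ax <- match(axis, axes)

  # (1) pre-strain baseline
  base <- settings
  base$sweeps <- as.integer(baseline_sweeps)
  pre <- run_mc(config, phase, base, ff)
  s <- pre$series
  lastq <- s[s$sweep > baseline_sweeps * 3 / 4, , drop = FALSE]
  L0 <- c(mean(lastq$Lx), mean(lastq$Ly), mean(lastq$Lz))
  has_lipids <- length(lipid_molecules(config)) >= 2
  d0 <- if (descriptor_every > 0 && has_lipids)
    membrane_descriptors(pre$config)$thickness else NA_real_

  # (2) strain to exactly (1 + eta) * L_axis(0)
  cfg <- pre$config
  fac <- (1 + eta) * L0[ax] / cfg$box[ax]
  cfg <- rescale_axial(cfg, fac - 1, axis)

  # (3) constrained relaxation: anneal bump, then phase temperature
  rset <- settings
  rset$fixed_axes <- union(settings$fixed_axes, axis)
  series <- list(); thick <- list(); done <- 0
  run_chunk <- function(n, temp) {
    rset$sweeps <<- as.integer(n)
    ph <- phase; ph$T <- temp
    out <- run_mc(cfg, ph, rset, ff)
    cfg <<- out$config
    sr <- out$series
    sr$sweep <- sr$sweep + done
    series[[length(series) + 1]] <<- sr
    done <<- done + n
  }
  stride <- if (descriptor_every > 0) descriptor_every else relax_sweeps
  plan <- data.frame(
    n = c(chunk_sizes(anneal_sweeps, stride),
          chunk_sizes(relax_sweeps - anneal_sweeps, stride)),
    temp = NA_real_)
  plan$temp <- ifelse(cumsum(plan$n) <= anneal_sweeps, phase$T_anneal, phase$T)
  for (r in seq_len(nrow(plan))) {
    run_chunk(plan$n[r], plan$temp[r])
    if (descriptor_every > 0 && has_lipids) {
      thick[[length(thick) + 1]] <-
        data.frame(sweep = done,
                   thickness = membrane_descriptors(cfg)$thickness)
    }
  }
  series <- do.call(rbind, series)

  # (4) traces and plateau estimates
  denom <- if (eta == 0) 1 else eta
  free <- setdiff(axes, union(axis, settings$fixed_axes))
  traces <- data.frame(sweep = series$sweep)
  nu <- list()
  window <- series$sweep > burn_in
  for (i in free) {
    Li <- series[[paste0("L", i)]]
    tr <- -(Li - L0[match(i, axes)]) / (denom * L0[match(i, axes)])
    traces[[paste0("nu_", i, axis)]] <- tr
    w <- tr[window]
    est <- mean(w)
    se <- block_stderr(w)
    sl <- stats::coef(stats::lm(w ~ series$sweep[window]))[2]
    conv <- abs(sl) < se / sum(window)
    nu[[length(nu) + 1]] <- data.frame(
      pair = paste0("nu_", i, axis), response = i, strain = axis,
      estimate = est, stderr = se, converged = conv)
  }
  nu <- do.call(rbind, nu)
  rownames(nu) <- NULL

  res <- list(eta = eta, axis = axis, L0 = stats::setNames(L0, axes),
              traces = traces, plateau_window = c(burn_in + 1, relax_sweeps),
              nu = nu, series = series, baseline = pre$series,
              config = cfg)
  if (descriptor_every > 0 && has_lipids) {
    th <- do.call(rbind, thick)
    th$trace <- -(th$thickness - d0) / (denom * d0)
    w <- th$trace[th$sweep > burn_in]
    res$thickness_trace <- th
    res$nu_thickness <- data.frame(
      pair = paste0("nu_d", axis), estimate = mean(w),
      stderr = stats::sd(w) / sqrt(length(w)))
  }
  structure(res, class = "poisson_result")
}

#' @export
print.poisson_result <- function(x, ...) {
  cat(sprintf("<poisson_result> strain eta = %g along %s\n", x$eta, x$axis))
  for (r in seq_len(nrow(x$nu)))
    cat(sprintf("  %s = %.4f +- %.4f%s\n", x$nu$pair[r], x$nu$estimate[r],
                x$nu$stderr[r],
                if (x$nu$converged[r]) "" else "  [not converged]"))
  if (!is.null(x$nu_thickness))
    cat(sprintf("  %s = %.4f +- %.4f (membrane thickness)\n",
                x$nu_thickness$pair, x$nu_thickness$estimate,
                x$nu_thickness$stderr))
  invisible(x)
}

#' Strain working-range scan
#'
#' Repeats [measure_poisson()] over a set of strains.  The estimate is
#' trustworthy where it is independent of `eta`: too large a strain damages
#' the membrane structure, too small a strain opens too little free volume
#' for particles to rearrange.
#'
#' @param config,phase,axis,settings,ff,... As in [measure_poisson()].
#' @param etas Strains to scan.
#' @return Data frame with one row per (eta, response axis).
#' @export
scan_eta <- function(config, phase, etas = c(0.025, 0.05, 0.1),
                     axis = "y", settings = mc_settings(sweeps = 0, seed = 1),
                     ff = forcefield_params(), ...) {
  out <- lapply(etas, function(e) {
    r <- measure_poisson(config, phase, eta = e, axis = axis,
                         settings = settings, ff = ff, ...)
    cbind(eta = e, r$nu)
  })
  do.call(rbind, out)
}

# standard error from block averaging (10 blocks), robust to short
# autocorrelation within the plateau window
block_stderr <- function(x, nblocks = 10) {
  n <- length(x)
  if (n < 2 * nblocks) return(stats::sd(x) / sqrt(max(n, 2)))
  bl <- split(x, cut(seq_len(n), nblocks, labels = FALSE))
  m <- vapply(bl, mean, numeric(1))
  stats::sd(m) / sqrt(length(m))
}
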