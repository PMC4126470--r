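#' Monte Carlo run settings
#'
#' One sweep attempts one random displacement per bead (uniform in a cube of
#' half-width `displacement_max`, Metropolis acceptance `min(1, exp(-dU/T))`)
#' followed by one box move per non-fixed axis: a uniform step in `ln L`
#' with affine rescaling of the coordinates along that axis, accepted with
#' `min(1, exp(-[dU + P dV - N T ln(V'/V)] / T))`.
#'
#' @param sweeps Number of sweeps.
#' @param displacement_max Half-width of the displacement cube (sigma_LJ).
#' @param box_move_max Half-width of the uniform step in `ln L`.
#' @param fixed_axes Character subset of `c("x","y","z")` whose box lengths
#'   are held constant (no box moves on those axes).
#' @param move_axes Axes along which beads are displaced (default all
#'   three; 2D toy systems freeze z).
#' @param seed Integer master seed, or `NULL` to continue the current RNG
#'   stream (used when chaining runs).
#' @param sample_every Record observables every this many sweeps.
#' @param adapt_acceptance Adapt `displacement_max` towards
#'   `target_acceptance` every 50 sweeps.  Use during equilibration only:
#'   adaptation breaks detailed balance, so it is off by default and must
#'   stay off during production and the Poisson relaxation.
#' @param target_acceptance Target displacement acceptance fraction.
#' @return An object of class `mc_settings`.
#' @export
mc_settings <- function(sweeps, displacement_max = 0.12, box_move_max = 0.002,
                        fixed_axes = character(0),
                        move_axes = c("x", "y", "z"), seed = NULL,
                        sample_every = 1, adapt_acceptance = FALSE,
                        target_acceptance = 0.4) {
  stopifnot(sweeps >= 0, displacement_max > 0, box_move_max > 0,
            all(fixed_axes %in% c("x", "y", "z")),
            all(move_axes %in% c("x", "y", "z")),
            target_acceptance > 0, target_acceptance < 1)
  structure(list(sweeps = as.integer(sweeps),
                 displacement_max = displacement_max,
                 box_move_max = box_move_max,
                 fixed_axes = unique(fixed_axes),
                 move_axes = unique(move_axes),
                 seed = seed, sample_every = as.integer(sample_every),
                 adapt_acceptance = isTRUE(adapt_acceptance),
                 target_acceptance = target_acceptance),
            class = "mc_settings")
}

#' Run NPT Metropolis Monte Carlo
#'
#' Samples the isothermal-isobaric ensemble of a configuration under the
#' model force field with single-bead displacements and per-axis ln-L box
#' moves (see [mc_settings()] for the move set and acceptance rules).  A
#' proposed move that would break a FENE bond is rejected, not fatal.  The
#' trajectory is fully determined by the RNG state: with
#' `settings$seed` set, two identical calls produce bit-identical output.
#'
#' @param config A [mem_config()] object.
#' @param phase A [phase_point()] giving P and T.
#' @param settings An [mc_settings()] object.
#' @param ff An [forcefield_params()] object.
#' @return A list with elements `config` (final configuration),
#'   `series` (data frame: sweep, Lx, Ly, Lz, energy, volume),
#'   `acceptance` (displacement and box fractions), `n_box_moves`,
#'   `energy` (final running energy) and `displacement_max_final`.
#' @export
run_mc <- function(config, phase, settings, ff = forcefield_params()) {
  stopifnot(inherits(config, "mem_config"), inherits(settings, "mc_settings"))
  if (!is.null(settings$seed)) set.seed(as.integer(settings$seed))
  if (settings$sweeps == 0) {
    return(list(config = config,
                series = empty_series(),
                acceptance = c(displacement = NA_real_, box = NA_real_),
                n_box_moves = 0, energy = as.numeric(total_energy(config, ff)),
                displacement_max_final = settings$displacement_max))
  }
  cc <- config_to_cpp(config)
  axes <- c("x", "y", "z")
  res <- cpp_run_mc(cc$positions, cc$kind, cc$box, cc$bonds, cc$angles,
                    ff_to_cpp(ff, config), cc$well,
                    phase$T, phase$P, settings$sweeps,
                    settings$displacement_max, settings$box_move_max,
                    axes %in% settings$fixed_axes,
                    axes %in% settings$move_axes,
                    settings$sample_every,
                    settings$adapt_acceptance, settings$target_acceptance)
  n_att <- settings$sweeps * nrow(config$positions)
  if (n_att >= 1000 && is.finite(res$acc_displacement) &&
      res$acc_displacement < 0.01)
    warning("displacement acceptance below 1%; step size is likely too large")
  out <- config
  out$positions <- res$positions
  out$box <- as.numeric(res$box)
  series <- as.data.frame(res$series)
  names(series) <- c("sweep", "Lx", "Ly", "Lz", "energy", "volume")
  list(config = out, series = series,
       acceptance = c(displacement = res$acc_displacement, box = res$acc_box),
       n_box_moves = res$n_box_moves, energy = res$energy,
       displacement_max_final = res$dmax_final)
}

empty_series <- function() {
  data.frame(sweep = numeric(0), Lx = numeric(0), Ly = numeric(0),
             Lz = numeric(0), energy = numeric(0), volume = numeric(0))
}

#' Build and equilibrate a bilayer at a phase point
#'
#' Convenience composition of [build_bilayer()] and [run_mc()] at the
#' (P, T) of the phase.  Membrane descriptors are recorded every
#' `descriptor_every` sweeps to make equilibration assessable.
#'
#' @param size Integer pair `c(nx, ny)`: lipids per row/column per leaflet.
#' @param phase A [phase_point()].
#' @param sweeps Number of equilibration sweeps.
#' @param seed Integer master seed.
#' @param descriptor_every Descriptor sampling stride (0 = never).
#' @param settings Optional [mc_settings()]; `sweeps` and `seed` are taken
#'   from the arguments above.
#' @param ... Passed to [build_bilayer()].
#' @param ff An [forcefield_params()] object.
#' @return As [run_mc()], plus `descriptors`: a data frame of descriptor
#'   trajectories (empty when `descriptor_every = 0`).
#' @export
equilibrate_phase <- function(size, phase, sweeps, seed = 1,
                              descriptor_every = 0, settings = NULL,
                              ff = forcefield_params(), ...) {
  cfg <- build_bilayer(size[1], size[2], phase, seed = seed, ff = ff, ...)
  if (is.null(settings)) settings <- mc_settings(sweeps = sweeps)
  settings$sweeps <- as.integer(sweeps)
  settings$seed <- NULL
  set.seed(as.integer(seed))
  if (sweeps == 0 || descriptor_every <= 0) {
    out <- run_mc(cfg, phase, settings, ff)
    out$descriptors <- data.frame()
    return(out)
  }
  chunks <- chunk_sizes(sweeps, descriptor_every)
  series <- list(); desc <- list(); done <- 0
  out <- NULL
  for (ch in chunks) {
    settings$sweeps <- as.integer(ch)
    out <- run_mc(cfg, phase, settings, ff)
    cfg <- out$config
    s <- out$series
    s$sweep <- s$sweep + done
    series[[length(series) + 1]] <- s
    done <- done + ch
    d <- membrane_descriptors(cfg)
    desc[[length(desc) + 1]] <-
      data.frame(sweep = done, chain_length_mean = d$chain_length_mean,
                 thickness = d$thickness, area_per_lipid = d$area_per_lipid,
                 order_parameter = d$order_parameter)
  }
  out$series <- do.call(rbind, series)
  out$descriptors <- do.call(rbind, desc)
  out
}

chunk_sizes <- function(total, chunk) {
  n <- total %/% chunk
  out <- rep(chunk, n)
  if (total %% chunk > 0) out <- c(out, total %% chunk)
  out
}
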