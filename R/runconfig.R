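#' Load a run configuration file
#'
#' Reads a YAML run configuration, validates every key against the schema
#' of defaults and returns the fully resolved configuration (defaults
#' applied).  Unknown keys and type mismatches are rejected by name.  The
#' defaults are the model's canonical values: the standard force-field
#' constants, the phase presets, a 2 sigma_LJ height grid, the
#' `0.5 <= q^2 <= 1` fit window, 400 anneal sweeps and a 5000-sweep
#' burn-in.
#'
#' @param path Path to a YAML file; an empty file resolves to all defaults.
#' @param overrides Optional named list applied on top of the file.
#' @return Nested named list of class `run_config`.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  defaults <- list(
    phase = "fluid",
    nx = 12L, ny = 24L,
    seed = 1L,
    forcefield = list(nu_fene = 100, r0 = 0.7, dr_m = 0.2, nu_ba = 4.7),
    mc = list(sweeps = 2e6, displacement_max = 0.12, box_move_max = 0.002,
              sample_every = 1L, adapt_acceptance = FALSE,
              target_acceptance = 0.4),
    builder = list(area_per_lipid = NULL, solvent_density = NULL,
                   solvent_pad = 6),
    poisson = list(eta = 0.05, axis = "y", relax_sweeps = 15000L,
                   anneal_sweeps = 400L, burn_in = 5000L,
                   baseline_sweeps = 4000L),
    spectrum = list(grid_spacing = 2, qsq_min = 0.5, qsq_max = 1,
                    frame_stride = 100L),
    output = list(dir = ".", trajectory = "traj.extxyz",
                  observables = "obs.csv", report = "report.json"))
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  if (!is.null(overrides)) user <- modify_checked(user, overrides, "override")
  resolved <- merge_config(defaults, user, "")
  class(resolved) <- "run_config"
  resolved
}

merge_config <- function(defaults, user, prefix) {
  if (length(user) == 0) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) > 0)
    stop("unknown configuration key: ", paste0(prefix, bad, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]]))
        stop("configuration key ", prefix, k, " must be a mapping")
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(prefix, k, "."))
    } else {
      v <- user[[k]]
      d <- defaults[[k]]
      if (!is.null(d) && is.numeric(d) && !is.numeric(v))
        stop("configuration key ", prefix, k, " must be numeric")
      if (!is.null(d) && is.character(d) && !is.character(v))
        stop("configuration key ", prefix, k, " must be a string")
      defaults[[k]] <- v
    }
  }
  defaults
}

modify_checked <- function(user, overrides, what) {
  for (k in names(overrides)) user[[k]] <- overrides[[k]]
  user
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
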