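#' Particle configuration container
#'
#' Holds bead positions, bead kinds, molecule topology and the periodic
#' simulation box of one snapshot.  Lipids are chains of 7 beads (one head
#' followed by six tail beads); solvent beads are single-bead molecules.
#' Bonds are derived from consecutive beads along each molecule chain unless
#' an explicit bond list is supplied (used by the toy spring networks, which
#' have no chain topology).  Angle triples are all consecutive bead triples
#' of each chain.
#'
#' @param positions N x 3 numeric matrix of coordinates (sigma_LJ).
#' @param kinds Character vector of length N with values
#'   `"head"`, `"tail"`, `"solvent"`.
#' @param molecules List of integer vectors; each vector lists the bead
#'   indices of one molecule in chain order (head first for lipids).
#' @param box Numeric length-3 vector of box edge lengths (sigma_LJ); the
#'   box is periodic on all three axes.
#' @param bonds Optional explicit 2-column integer matrix of bonded pairs;
#'   default: consecutive beads of each molecule chain.
#' @param bond_style `"fene"` (default) or `"harmonic"`.
#' @param bond_params For `bond_style = "harmonic"`: `list(k =, r0 =)`.
#' @param use_angles Apply the bond-angle potential to chain triples
#'   (default `TRUE`; toy networks set `FALSE`).
#' @param well Optional external harmonic well `list(k =, center = c(x,y,z))`
#'   acting on every bead; a test hook for canonical-sampling checks.
#' @return An object of class `mem_config`.
#' @export
mem_config <- function(positions, kinds, molecules, box, bonds = NULL,
                       bond_style = c("fene", "harmonic"), bond_params = NULL,
                       use_angles = TRUE, well = NULL) {
  bond_style <- match.arg(bond_style)
  positions <- unname(as.matrix(positions))
  stopifnot(ncol(positions) == 3, is.numeric(positions))
  n <- nrow(positions)
  kinds <- as.character(kinds)
  if (length(kinds) != n) stop("kinds must have one entry per bead")
  if (!all(kinds %in% c("head", "tail", "solvent")))
    stop("kinds must be head/tail/solvent")
  box <- as.numeric(box)
  stopifnot(length(box) == 3, all(box > 0))
  molecules <- lapply(molecules, as.integer)
  idx <- sort(unlist(molecules))
  if (!identical(as.integer(idx), seq_len(n)))
    stop("molecules must partition bead indices 1..N")
  if (is.null(bonds)) {
    bonds <- do.call(rbind, lapply(molecules, function(m) {
      if (length(m) < 2) return(NULL)
      cbind(m[-length(m)], m[-1])
    }))
    if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (bond_style == "harmonic" &&
      (is.null(bond_params) || is.null(bond_params$k) || is.null(bond_params$r0)))
    stop("harmonic bond_style requires bond_params = list(k =, r0 =)")
  # wrap into the primary box
  for (a in 1:3) positions[, a] <- positions[, a] %% box[a]
  structure(list(positions = positions, kinds = kinds, molecules = molecules,
                 box = box, bonds = bonds, bond_style = bond_style,
                 bond_params = bond_params, use_angles = isTRUE(use_angles),
                 well = well),
            class = "mem_config")
}

#' @export
print.mem_config <- function(x, ...) {
  nk <- table(factor(x$kinds, levels = c("head", "tail", "solvent")))
  cat("<mem_config> ", nrow(x$positions), " beads (",
      nk[["head"]], " head, ", nk[["tail"]], " tail, ",
      nk[["solvent"]], " solvent), ",
      length(x$molecules), " molecules\n", sep = "")
  cat(sprintf("  box: %.4f x %.4f x %.4f sigma_LJ, bonds: %d (%s)\n",
              x$box[1], x$box[2], x$box[3], nrow(x$bonds), x$bond_style))
  invisible(x)
}

# angle triples (consecutive) from the molecule chains
config_angles <- function(config) {
  if (!config$use_angles) return(matrix(integer(0), 0, 3))
  ang <- do.call(rbind, lapply(config$molecules, function(m) {
    if (length(m) < 3) return(NULL)
    cbind(m[1:(length(m) - 2)], m[2:(length(m) - 1)], m[3:length(m)])
  }))
  if (is.null(ang)) matrix(integer(0), 0, 3) else matrix(as.integer(ang), ncol = 3)
}

# numeric payload for the C++ engine (0-based kind codes stay 1-based here;
# the engine subtracts from bond/angle indices, kinds are passed as 0..2)
config_to_cpp <- function(config) {
  kind <- match(config$kinds, c("head", "tail", "solvent")) - 1L
  well <- config$well
  if (!is.null(well)) well <- list(k = well$k, center = as.numeric(well$center))
  list(positions = config$positions, kind = kind, box = config$box,
       bonds = config$bonds, angles = config_angles(config),
       well = if (is.null(well)) NULL else well)
}

# indices of lipid molecules (7-bead chains with a head bead first)
lipid_molecules <- function(config) {
  Filter(function(m) length(m) == 7 && config$kinds[m[1]] == "head",
         config$molecules)
}

#' Bond lengths of a configuration
#'
#' Minimum-image lengths of every bond, in bond-list order.
#'
#' @param config A [mem_config()] object.
#' @return Numeric vector of lengths (sigma_LJ).
#' @export
bond_lengths <- function(config) {
  b <- config$bonds
  if (nrow(b) == 0) return(numeric(0))
  d <- config$positions[b[, 1], , drop = FALSE] -
    config$positions[b[, 2], , drop = FALSE]
  for (a in 1:3) {
    L <- config$box[a]
    d[, a] <- d[, a] - L * round(d[, a] / L)
  }
  sqrt(rowSums(d^2))
}
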