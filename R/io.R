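#' Write a configuration as extended XYZ
#'
#' One frame per call (append for trajectories).  The comment line carries
#' the periodic box as a `Lattice` record and a
#' `Properties=species:S:1:pos:R:3:mol:I:1` declaration, so frames open in
#' standard molecular viewers.  Species symbols are `H` (head), `T` (tail)
#' and `S` (solvent).  Chain topology cannot be represented in XYZ, so the
#' molecule chains (plus bond style) are written to a JSON sidecar
#' `<path>.top.json` unless `sidecar = FALSE`.
#'
#' @param config A [mem_config()] object.
#' @param path Output file path.
#' @param append Append as an extra frame instead of overwriting.
#' @param sidecar Write/update the topology sidecar.
#' @export
write_extxyz <- function(config, path, append = FALSE, sidecar = TRUE) {
  n <- nrow(config$positions)
  sym <- c(head = "H", tail = "T", solvent = "S")[config$kinds]
  mol <- integer(n)
  for (m in seq_along(config$molecules)) mol[config$molecules[[m]]] <- m
  lat <- sprintf("%.17g 0 0 0 %.17g 0 0 0 %.17g",
                 config$box[1], config$box[2], config$box[3])
  hdr <- sprintf(
    'Lattice="%s" Properties=species:S:1:pos:R:3:mol:I:1 pbc="T T T"', lat)
  lines <- c(
    as.character(n), hdr,
    sprintf("%s %.17g %.17g %.17g %d", sym, config$positions[, 1],
            config$positions[, 2], config$positions[, 3], mol))
  con <- file(path, if (append) "a" else "w")
  writeLines(lines, con)
  close(con)
  if (sidecar) {
    top <- list(molecules = lapply(config$molecules, as.integer),
                bond_style = config$bond_style,
                bond_params = config$bond_params,
                use_angles = config$use_angles)
    if (!is.null(config$bonds) && config$bond_style == "harmonic")
      top$bonds <- apply(config$bonds, 1, as.integer, simplify = FALSE)
    jsonlite::write_json(top, paste0(path, ".top.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read an extended-XYZ frame
#'
#' Reads frame `frame` (1-based) of an extended-XYZ file written by
#' [write_extxyz()], restoring positions, kinds, box and -- via the JSON
#' sidecar, if present -- the molecule topology.  The round trip is
#' bit-identical.
#'
#' @param path File path.
#' @param frame Frame number (default 1).
#' @return A [mem_config()] object.
#' @export
read_extxyz <- function(path, frame = 1) {
  lines <- readLines(path)
  at <- 1; fr <- 0
  while (at <= length(lines)) {
    n <- as.integer(lines[at])
    fr <- fr + 1
    if (fr == frame) break
    at <- at + n + 2
  }
  if (fr != frame) stop("frame ", frame, " not found in ", path)
  hdr <- lines[at + 1]
  lat <- regmatches(hdr, regexpr('Lattice="[^"]*"', hdr))
  if (length(lat) == 0) stop("extxyz header lacks a Lattice record")
  lv <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat), "\\s+")[[1]])
  box <- lv[c(1, 5, 9)]
  rows <- strsplit(trimws(lines[at + 2:(n + 1)]), "\\s+")
  sym <- vapply(rows, `[`, character(1), 1)
  pos <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  kinds <- c(H = "head", T = "tail", S = "solvent")[sym]
  side <- paste0(path, ".top.json")
  if (file.exists(side)) {
    top <- jsonlite::read_json(side, simplifyVector = TRUE)
    mols <- lapply(top$molecules, as.integer)
    bonds <- if (is.null(top$bonds)) NULL
      else if (is.matrix(top$bonds)) matrix(as.integer(top$bonds), ncol = 2)
      else matrix(as.integer(unlist(top$bonds)), ncol = 2, byrow = TRUE)
    bp <- top$bond_params
    mem_config(pos, kinds, mols, box, bonds = bonds,
               bond_style = top$bond_style,
               bond_params = if (is.null(bp)) NULL else as.list(bp),
               use_angles = isTRUE(top$use_angles))
  } else {
    mol <- as.integer(vapply(rows, `[`, character(1), 5))
    mols <- split(seq_len(n), mol)
    names(mols) <- NULL
    mem_config(pos, kinds, mols, box)
  }
}

#' Write an observable series as CSV
#'
#' Plain CSV with a header row, preceded by `#`-prefixed comment lines
#' recording the units of every column; read back with
#' [read_observables()].
#'
#' @param series Data frame as produced by [run_mc()].
#' @param path Output path.
#' @export
write_observables <- function(series, path) {
  units <- c(sweep = "sweeps", Lx = "sigma_LJ", Ly = "sigma_LJ",
             Lz = "sigma_LJ", energy = "epsilon", volume = "sigma_LJ^3")
  u <- units[names(series)]
  u[is.na(u)] <- "dimensionless"
  con <- file(path, "w")
  writeLines(paste0("# units: ", paste(names(series), u, sep = "=",
                                       collapse = " ")), con)
  utils::write.csv(series, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_observables
#' @export
read_observables <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write a JSON result report
#'
#' Adds provenance (package version, timestamp, the resolved run
#' configuration and its MD5 hash, and the master seed) around a list of
#' results.
#'
#' @param results Named list of result objects (coerced by jsonlite).
#' @param path Output path.
#' @param config Optional resolved [load_config()] list.
#' @param seed Optional master seed to record.
#' @export
write_report <- function(results, path, config = NULL, seed = NULL) {
  prov <- list(package = "memelast",
               version = as.character(utils::packageVersion("memelast")),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(seed)) prov$seed <- seed
  if (!is.null(config)) {
    config <- unclass(config)
    tmp <- tempfile()
    jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
    prov$config <- config
    prov$config_md5 <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  jsonlite::write_json(c(list(provenance = prov), results), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
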