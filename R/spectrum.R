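#' Membrane height field on a regular grid
#'
#' Discretises the lateral plane into a grid of target spacing
#' `spacing` (default 2 sigma_LJ), computes in every cell the mean head-bead
#' heights `z_+` and `z_-` of the upper and lower leaflet, and defines the
#' local membrane height as the midplane `h = (z_+ + z_-) / 2` with the
#' grid average subtracted.  Cells left empty by one leaflet are filled by
#' iterating the average of their non-empty 4-neighbourhood (periodic).
#'
#' @param config A [mem_config()] bilayer configuration.
#' @param spacing Target grid spacing (sigma_LJ); the actual spacing is
#'   `L / round(L / spacing)` per axis.
#' @param max_empty_frac Error if more than this fraction of cells is empty
#'   in either leaflet (ruptured membrane or too fine a grid).
#' @return An object of class `height_field`: list with the zero-mean
#'   matrix `h` (nx x ny), `box = c(Lx, Ly)`, `spacing`, and the empty-cell
#'   counts per leaflet.
#' @export
height_field <- function(config, spacing = 2, max_empty_frac = 0.1) {
  lip <- lipid_molecules(config)
  if (length(lip) < 2) stop("configuration holds no bilayer")
  pos <- config$positions
  Lx <- config$box[1]; Ly <- config$box[2]
  nx <- max(2, round(Lx / spacing)); ny <- max(2, round(Ly / spacing))
  heads <- vapply(lip, `[`, integer(1), 1)
  hx <- pos[heads, 1]; hy <- pos[heads, 2]; hz <- pos[heads, 3]
  mid <- mean(pos[unlist(lip), 3])
  upper <- hz > mid
  if (!any(upper) || all(upper)) stop("leaflet identification failed")
  cx <- pmin(floor(hx / Lx * nx), nx - 1) + 1
  cy <- pmin(floor(hy / Ly * ny), ny - 1) + 1

  leaflet_grid <- function(sel) {
    g <- matrix(NA_real_, nx, ny)
    cnt <- matrix(0, nx, ny)
    zs <- matrix(0, nx, ny)
    for (k in which(sel)) {
      zs[cx[k], cy[k]] <- zs[cx[k], cy[k]] + hz[k]
      cnt[cx[k], cy[k]] <- cnt[cx[k], cy[k]] + 1
    }
    g[cnt > 0] <- zs[cnt > 0] / cnt[cnt > 0]
    list(g = g, empty = sum(cnt == 0))
  }
  up <- leaflet_grid(upper)
  lo <- leaflet_grid(!upper)
  for (lf in list(up, lo)) {
    if (lf$empty > max_empty_frac * nx * ny)
      stop(sprintf("%d of %d grid cells empty in one leaflet (> %.0f%%): %s",
                   lf$empty, nx * ny, 100 * max_empty_frac,
                   "membrane ruptured or grid too fine"))
  }
  zp <- fill_empty_cells(up$g)
  zm <- fill_empty_cells(lo$g)
  h <- (zp + zm) / 2
  h <- h - mean(h)
  structure(list(h = h, box = c(Lx, Ly),
                 spacing = c(Lx / nx, Ly / ny),
                 n_empty = c(upper = up$empty, lower = lo$empty)),
            class = "height_field")
}

# iterated periodic 4-neighbour averaging of NA cells
fill_empty_cells <- function(g, max_iter = 100) {
  nx <- nrow(g); ny <- ncol(g)
  for (it in seq_len(max_iter)) {
    na <- which(is.na(g), arr.ind = TRUE)
    if (nrow(na) == 0) return(g)
    new_vals <- rep(NA_real_, nrow(na))
    for (r in seq_len(nrow(na))) {
      i <- na[r, 1]; j <- na[r, 2]
      nb <- c(g[(i %% nx) + 1, j], g[((i - 2) %% nx) + 1, j],
              g[i, (j %% ny) + 1], g[i, ((j - 2) %% ny) + 1])
      nb <- nb[!is.na(nb)]
      if (length(nb) > 0) new_vals[r] <- mean(nb)
    }
    g[na] <- new_vals
  }
  if (anyNA(g)) stop("empty-cell filling did not converge")
  g
}

# helper: build a height_field directly from a matrix (used by the synthetic
# Helfrich sampler and by tests)
new_height_field <- function(h, box) {
  h <- h - mean(h)
  structure(list(h = h, box = as.numeric(box),
                 spacing = c(box[1] / nrow(h), box[2] / ncol(h)),
                 n_empty = c(upper = 0L, lower = 0L)),
            class = "height_field")
}

#' Height-fluctuation power spectrum
#'
#' Discrete Fourier transform of the gridded height field, normalised to
#' the continuum Fourier-series convention
#' `h_hat(q) = A_cell * sum_ij h(i,j) exp(-i q . r_ij)` so that Parseval's
#' identity `sum_q |h_hat(q)|^2 / (Lx Ly) = A_cell * sum_ij h_ij^2` holds
#' exactly and the Helfrich prediction
#' `<|h_hat(q)|^2> = k_B T L^2 / (k_c q^4 + sigma q^2)` applies directly.
#' The zero mode is excluded (the field is mean-subtracted).
#'
#' @param field A [height_field()].
#' @return Data frame with one row per Fourier mode: `qx`, `qy`, `q`,
#'   `q2` and `power` (`|h_hat|^2`), with the box area as attribute
#'   `"area"`.
#' @export
power_spectrum <- function(field) {
  h <- field$h
  nx <- nrow(h); ny <- ncol(h)
  if (nx < 4 || ny < 4) stop("grid must be at least 4x4")
  Lx <- field$box[1]; Ly <- field$box[2]
  acell <- (Lx / nx) * (Ly / ny)
  H <- stats::fft(h) * acell
  kx <- 0:(nx - 1); kx[kx > nx / 2] <- kx[kx > nx / 2] - nx
  ky <- 0:(ny - 1); ky[ky > ny / 2] <- ky[ky > ny / 2] - ny
  qx <- 2 * pi * outer(kx / Lx, rep(1, ny))
  qy <- 2 * pi * outer(rep(1, nx), ky / Ly)
  df <- data.frame(qx = as.vector(qx), qy = as.vector(qy),
                   power = as.vector(Mod(H)^2))
  df$q2 <- df$qx^2 + df$qy^2
  df$q <- sqrt(df$q2)
  df <- df[df$q2 > 0, c("qx", "qy", "q", "q2", "power")]
  attr(df, "area") <- Lx * Ly
  attr(df, "box") <- c(Lx, Ly)
  df
}

#' Average mode powers over decorrelated frames
#'
#' @param fields List of [height_field()] objects on identical grids (the
#'   frames are assumed decorrelated at the sampling stride).
#' @return Data frame as [power_spectrum()] with `power` averaged over
#'   frames; attributes `"area"` and `"n_frames"`.
#' @export
spectrum_average <- function(fields) {
  stopifnot(length(fields) >= 1)
  specs <- lapply(fields, power_spectrum)
  out <- specs[[1]]
  if (length(specs) > 1) {
    pw <- vapply(specs, function(s) s$power, numeric(nrow(out)))
    out$power <- rowMeans(pw)
  }
  attr(out, "area") <- attr(specs[[1]], "area")
  attr(out, "box") <- attr(specs[[1]], "box")
  attr(out, "n_frames") <- length(fields)
  out
}

#' Fit the Helfrich undulation spectrum
#'
#' Least-squares fit of the inverted spectrum
#' `y(q) = k_B T L^2 / (<|h_hat(q)|^2> q^2) = k_c q^2 + sigma`,
#' linear in `q^2`, over the fit window `0.5 <= q^2 <= 1` (default): below
#' it the finite box size distorts the modes, above it the bead
#' discreteness does.  Modes are radially binned by `|q|` with bin width
#' `2 pi / max(Lx, Ly)` before fitting (set `binned = FALSE` to fit raw
#' modes).
#'
#' @param spectrum Output of [spectrum_average()] (or [power_spectrum()]).
#' @param T Temperature (epsilon / k_B).
#' @param window Length-2 numeric: the `q^2` fit window.
#' @param binned Radially bin modes before fitting (default `TRUE`).
#' @return An object of class `helfrich_fit`: `k_c` and `sigma_tension`
#'   with standard errors, the fit window, the per-bin data, residual
#'   standard error, and flags (`ok`, `undersampled`).
#' @export
fit_helfrich <- function(spectrum, T, window = c(0.5, 1), binned = TRUE) {
  area <- attr(spectrum, "area")
  if (is.null(area)) stop("spectrum lacks its box-area attribute")
  n_frames <- attr(spectrum, "n_frames")
  if (is.null(n_frames)) n_frames <- 1
  df <- spectrum
  if (any(df$power <= 0) && all(df$power <= 0))
    stop("zero fluctuation power in every mode: frames carry no height signal")
  if (binned) {
    box <- attr(spectrum, "box")
    if (is.null(box)) box <- rep(sqrt(area), 2)
    wq <- 2 * pi / max(box)
    bin <- floor(df$q / wq + 0.5)
    df <- do.call(rbind, lapply(split(df, bin), function(b) {
      data.frame(q = mean(b$q), q2 = mean(b$q2), power = mean(b$power),
                 n_modes = nrow(b))
    }))
  } else {
    df$n_modes <- 1
  }
  sel <- df$q2 >= window[1] & df$q2 <= window[2]
  if (sum(sel) < 3) stop("fewer than 3 q-bins inside the fit window")
  d <- df[sel, ]
  if (any(d$power <= 0))
    stop("zero fluctuation power inside the fit window")
  d$y <- T * area / (d$power * d$q2)
  # the sampling variance of a bin's mean power scales as 1/n_modes, so
  # bins are weighted by the number of modes they average over
  fit <- stats::lm(y ~ q2, data = d, weights = d$n_modes)
  co <- summary(fit)$coefficients
  kc <- co["q2", "Estimate"]
  structure(list(
    k_c = kc, k_c_se = co["q2", "Std. Error"],
    sigma_tension = co["(Intercept)", "Estimate"],
    sigma_se = co["(Intercept)", "Std. Error"],
    fit_window = window, n_bins = nrow(d), modes = d,
    residual = summary(fit)$sigma,
    n_frames = n_frames,
    undersampled = n_frames < 2,
    ok = is.finite(kc) && kc > 0),
    class = "helfrich_fit")
}

#' @export
print.helfrich_fit <- function(x, ...) {
  cat(sprintf(paste0("<helfrich_fit> k_c = %.4f +- %.4f epsilon, sigma = ",
                     "%.4f +- %.4f epsilon/sigma_LJ^2\n"),
              x$k_c, x$k_c_se, x$sigma_tension, x$sigma_se))
  cat(sprintf("  window %.2f <= q^2 <= %.2f, %d bins, %d frame(s)%s%s\n",
              x$fit_window[1], x$fit_window[2], x$n_bins, x$n_frames,
              if (x$undersampled) ", undersampled" else "",
              if (x$ok) "" else ", FIT FAILED (k_c <= 0)"))
  invisible(x)
}
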