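#' Synthetic Helfrich height-field ensemble
#'
#' Draws i.i.d. height-field frames whose Fourier modes follow the Helfrich
#' spectrum exactly: each mode's complex amplitude has independent Gaussian
#' real and imaginary parts with total variance
#' `k_B T L^2 / (k_c q^4 + sigma q^2)`, Hermitian-symmetrised so every
#' generated real-space field is real.  The ensemble is both the analytic
#' oracle for [fit_helfrich()] and a fixture generator: fitting it must
#' recover the generating `k_c` and `sigma_tension`.
#'
#' @param k_c Bending rigidity (epsilon).
#' @param sigma_tension Surface tension (epsilon/sigma_LJ^2).
#' @param T Temperature (epsilon/k_B).
#' @param L Lateral box edge (sigma_LJ); the grid spacing is `L / grid_n`.
#' @param grid_n Grid points per axis (>= 4).
#' @param frames Number of frames (>= 1).
#' @param seed Integer seed.
#' @return List of `frames` [height_field()] objects.
#' @export
make_helfrich_ensemble <- function(k_c, sigma_tension = 0, T = 1.3, L = 64,
                                   grid_n = 32, frames = 100, seed = 1) {
  stopifnot(grid_n >= 4, frames >= 1)
  if (k_c == 0 && sigma_tension == 0)
    stop("k_c and sigma_tension cannot both be zero: amplitudes undefined")
  set.seed(as.integer(seed))
  n <- grid_n
  acell <- (L / n)^2
  k <- 0:(n - 1); k[k > n / 2] <- k[k > n / 2] - n
  qx <- 2 * pi * outer(k / L, rep(1, n))
  qy <- 2 * pi * outer(rep(1, n), k / L)
  q2 <- qx^2 + qy^2
  S <- matrix(0, n, n)
  nz <- q2 > 0
  S[nz] <- T * L^2 / (k_c * q2[nz]^2 + sigma_tension * q2[nz])
  # conjugate-partner linear indices: partner of (i, j) is ((n-i) mod n,
  # (n-j) mod n) in 0-based index space
  ii <- matrix(rep(0:(n - 1), n), n, n)
  jj <- t(ii)
  partner <- ((n - ii) %% n) + n * ((n - jj) %% n) + 1
  lin <- ii + n * jj + 1
  self_conj <- partner == lin & nz
  primary <- lin < partner & nz
  p_idx <- lin[primary]
  c_idx <- partner[primary]
  s_idx <- lin[self_conj]
  amp <- sqrt(S[p_idx] / 2)
  samp <- sqrt(S[s_idx])

  lapply(seq_len(frames), function(f) {
    H <- matrix(complex(real = 0, imaginary = 0), n, n)
    zp <- complex(real = stats::rnorm(length(p_idx), sd = amp),
                  imaginary = stats::rnorm(length(p_idx), sd = amp))
    H[p_idx] <- zp
    H[c_idx] <- Conj(zp)
    H[s_idx] <- complex(real = stats::rnorm(length(s_idx), sd = samp))
    # h_hat(q) = A_cell * fft(h)  =>  fft(h) = H / A_cell
    h <- stats::fft(H / acell, inverse = TRUE) / (n * n)
    if (max(abs(Im(h))) > 1e-10)
      stop("Hermitian symmetrisation failed: field is not real")
    new_height_field(Re(h), c(L, L))
  })
}

#' Periodic 2D triangular lattice of harmonic springs
#'
#' Builds an `n x n` triangular lattice of nodes connected to their six
#' nearest neighbours by identical central-force harmonic springs at rest
#' length `spacing`, periodic in x and y.  In the continuum limit this
#' network has Poisson's ratio 1/3, which makes it the analytic oracle for
#' the box-rescaling protocol: the protocol machinery (NPT Monte Carlo,
#' strain, relaxation) is exactly the one used for bilayers, demonstrating
#' that the method is model-agnostic.
#'
#' Nodes are coded as solvent beads, whose mutual pair interaction is
#' inactive, so the only interactions are the explicit springs.
#'
#' @param n Nodes per row and per column (even, >= 4; odd n is rounded up
#'   to keep the periodic row offset consistent).
#' @param spacing Rest length of the springs (sigma_LJ).
#' @param stiffness Spring constant (epsilon/sigma_LJ^2).
#' @param jitter Uniform random initial displacement amplitude (sigma_LJ).
#' @param seed Integer seed for the jitter.
#' @return A [mem_config()] with harmonic bonds and a thin periodic z box.
#' @export
make_triangular_network <- function(n = 8, spacing = 1, stiffness = 100,
                                    jitter = 0, seed = 1) {
  stopifnot(n >= 4)
  if (n %% 2 == 1) n <- n + 1
  a <- spacing
  hy <- a * sqrt(3) / 2
  Lx <- n * a; Ly <- n * hy
  idx <- function(i, j) ((j %% n) * n + (i %% n)) + 1  # 0-based i, j
  pos <- matrix(0, n * n, 3)
  for (j in 0:(n - 1)) {
    for (i in 0:(n - 1)) {
      pos[idx(i, j), 1] <- (i + 0.5 * (j %% 2)) * a
      pos[idx(i, j), 2] <- j * hy
    }
  }
  bonds <- list()
  for (j in 0:(n - 1)) {
    for (i in 0:(n - 1)) {
      me <- idx(i, j)
      # right neighbour, and the two neighbours in the row above
      up_shift <- if (j %% 2 == 1) 1 else -1
      bonds[[length(bonds) + 1]] <- c(me, idx(i + 1, j))
      bonds[[length(bonds) + 1]] <- c(me, idx(i, j + 1))
      bonds[[length(bonds) + 1]] <- c(me, idx(i + up_shift, j + 1))
    }
  }
  bonds <- do.call(rbind, bonds)
  if (jitter > 0) {
    set.seed(as.integer(seed))
    pos[, 1:2] <- pos[, 1:2] + matrix(stats::runif(2 * n * n, -jitter, jitter),
                                      n * n, 2)
  }
  pos[, 3] <- 0.5  # flat sheet in a thin z slab
  mem_config(pos, rep("solvent", n * n), as.list(seq_len(n * n)),
             box = c(Lx, Ly, 1), bonds = bonds, bond_style = "harmonic",
             bond_params = list(k = stiffness, r0 = spacing),
             use_angles = FALSE)
}

#' Phantom-gas configuration
#'
#' `n` solvent beads placed uniformly at random in the box.  Solvent beads
#' do not interact with each other, so the total energy is exactly zero
#' and an NPT run samples the ideal-gas isobaric ensemble: the analytic
#' oracle `<V> = n T / P` for the barostat.
#'
#' @param n Number of beads (>= 1).
#' @param box Numeric length-3 box edge lengths (sigma_LJ).
#' @param seed Integer seed.
#' @return A [mem_config()].
#' @export
make_phantom_gas <- function(n, box = c(5, 5, 5), seed = 1) {
  stopifnot(n >= 1, length(box) == 3)
  set.seed(as.integer(seed))
  pos <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
               stats::runif(n, 0, box[3]))
  mem_config(pos, rep("solvent", n), as.list(seq_len(n)), box = box)
}
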