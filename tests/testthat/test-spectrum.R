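test_that("the height field is flat for built bilayers and shift-invariant", {
  cfg <- build_bilayer(8, 8, phase_point("fluid"), solvent_density = 0,
                       solvent_pad = 2, seed = 1)
  hf <- height_field(cfg)
  expect_equal(max(abs(hf$h)), 0, tolerance = 1e-10)
  shifted <- cfg
  shifted$positions[, 3] <- (shifted$positions[, 3] + 1.7) %% cfg$box[3]
  expect_equal(height_field(shifted)$h, hf$h, tolerance = 1e-10)
})

test_that("a corrugated bilayer's height field recovers the cosine", {
  amp <- 0.8; L <- 32; n <- 16
  cfg <- corrugated_bilayer(n = n, L = L, amp = amp)
  hf <- height_field(cfg, spacing = 2)
  # heads sit at cell centres: expected height is the cosine at the centre
  xc <- (seq_len(n) - 0.5) * (L / n)
  expected <- amp * cos(2 * pi * xc / L)
  expected <- expected - mean(expected)
  expect_equal(hf$h, matrix(expected, n, n), tolerance = 1e-9)
})

test_that("the power spectrum matches the analytic DFT of a cosine", {
  n <- 16; L <- 32; amp <- 0.5
  x <- (seq_len(n) - 0.5) * (L / n)
  h <- matrix(amp * cos(2 * pi * x / L), n, n)
  hf <- memelast:::new_height_field(h, c(L, L))
  ps <- power_spectrum(hf)
  acell <- (L / n)^2
  # all power in the (+-1, 0) modes: |h_hat| = A_cell * n^2 * amp / 2
  expected <- (acell * n^2 * amp / 2)^2
  hot <- ps[abs(ps$power) > 1e-12, ]
  expect_identical(nrow(hot), 2L)
  expect_equal(sort(hot$qx), c(-1, 1) * 2 * pi / L, tolerance = 1e-12)
  expect_equal(hot$power, rep(expected, 2), tolerance = 1e-9)
  # zero field gives zero power everywhere
  ps0 <- power_spectrum(memelast:::new_height_field(matrix(0, n, n), c(L, L)))
  expect_true(all(ps0$power == 0))
})

test_that("Parseval's identity holds to near machine precision", {
  for (seed in 1:3) {
    ens <- make_helfrich_ensemble(5.2, 0.5, T = 1.3, L = 64, grid_n = 32,
                                  frames = 1, seed = seed)
    hf <- ens[[1]]
    ps <- power_spectrum(hf)
    acell <- prod(hf$spacing)
    lhs <- sum(ps$power) / attr(ps, "area")
    rhs <- acell * sum(hf$h^2)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("white noise has a flat spectrum", {
  set.seed(8)
  n <- 32; L <- 64
  pw <- rowMeans(vapply(1:50, function(f) {
    hf <- memelast:::new_height_field(matrix(rnorm(n * n), n, n), c(L, L))
    power_spectrum(hf)$power
  }, numeric(n * n - 1)))
  ps <- power_spectrum(memelast:::new_height_field(matrix(rnorm(n * n), n, n),
                                                   c(L, L)))
  low <- mean(pw[ps$q2 < 0.5]); high <- mean(pw[ps$q2 >= 2])
  expect_equal(low / high, 1, tolerance = 0.1)
})

test_that("the Helfrich fit recovers generator parameters", {
  ens <- make_helfrich_ensemble(5.2, 0, T = 1.3, L = 128, grid_n = 64,
                                frames = 300, seed = 12)
  fit <- fit_helfrich(spectrum_average(ens), T = 1.3)
  expect_true(fit$ok)
  expect_equal(fit$k_c, 5.2, tolerance = 0.1)
  # tensionless ensembles: the pooled sigma estimate is consistent with zero
  sig <- vapply(1:5, function(s) {
    f <- fit_helfrich(spectrum_average(
      make_helfrich_ensemble(5.2, 0, T = 1.3, L = 128, grid_n = 64,
                             frames = 200, seed = s)), T = 1.3)
    c(f$sigma_tension, f$sigma_se)
  }, numeric(2))
  expect_lt(abs(mean(sig[1, ])), 3 * mean(sig[2, ]) / sqrt(5))
  # with tension: both parameters recovered
  ens2 <- make_helfrich_ensemble(5.2, 1, T = 1.3, L = 128, grid_n = 64,
                                 frames = 300, seed = 13)
  fit2 <- fit_helfrich(spectrum_average(ens2), T = 1.3)
  expect_equal(fit2$k_c, 5.2, tolerance = 0.1)
  expect_equal(fit2$sigma_tension, 1, tolerance = 0.25)
})

test_that("degenerate spectra are flagged or rejected", {
  n <- 16; L <- 32
  flat <- memelast:::new_height_field(matrix(0, n, n), c(L, L))
  spec <- spectrum_average(list(flat, flat, flat))
  expect_error(fit_helfrich(spec, T = 1.3), "zero fluctuation power")
  one <- make_helfrich_ensemble(5.2, 0, T = 1.3, L = 64, grid_n = 32,
                                frames = 1, seed = 2)
  fit1 <- fit_helfrich(spectrum_average(one), T = 1.3)
  expect_true(fit1$undersampled)
  tiny <- memelast:::new_height_field(matrix(rnorm(9), 3, 3), c(6, 6))
  expect_error(power_spectrum(tiny), "at least 4x4")
})

test_that("generated Helfrich fields are real and seeded", {
  a <- make_helfrich_ensemble(5.2, 0, T = 1.3, L = 64, grid_n = 16,
                              frames = 3, seed = 5)
  b <- make_helfrich_ensemble(5.2, 0, T = 1.3, L = 64, grid_n = 16,
                              frames = 3, seed = 5)
  expect_identical(a[[1]]$h, b[[1]]$h)
  expect_identical(a[[3]]$h, b[[3]]$h)
  expect_true(all(vapply(a, function(f) is.numeric(f$h) &&
                           abs(mean(f$h)) < 1e-12, logical(1))))
  # doubling the temperature doubles every expected mode power
  set.seed(1)
  pw1 <- rowMeans(vapply(make_helfrich_ensemble(5.2, 0, T = 1.3, L = 64,
                                                grid_n = 16, frames = 400,
                                                seed = 6),
                         function(f) power_spectrum(f)$power, numeric(255)))
  pw2 <- rowMeans(vapply(make_helfrich_ensemble(5.2, 0, T = 2.6, L = 64,
                                                grid_n = 16, frames = 400,
                                                seed = 7),
                         function(f) power_spectrum(f)$power, numeric(255)))
  expect_equal(mean(pw2 / pw1), 2, tolerance = 0.15)
  expect_error(make_helfrich_ensemble(0, 0, T = 1, L = 64, grid_n = 16),
               "cannot both be zero")
})
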