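test_that("axial rescaling is exact, invertible and axis-local", {
  cfg <- small_bilayer()
  expect_identical(rescale_axial(cfg, 0, "y")$positions, cfg$positions)
  eta <- 0.04
  fwd <- rescale_axial(cfg, eta, "y")
  back <- rescale_axial(fwd, -eta / (1 + eta), "y")
  expect_equal(back$positions, cfg$positions, tolerance = 1e-12)
  expect_equal(back$box, cfg$box, tolerance = 1e-12)
  # coordinate-wise: y scaled, x and z untouched
  expect_equal(fwd$positions[, 2], cfg$positions[, 2] * (1 + eta))
  expect_identical(fwd$positions[, c(1, 3)], cfg$positions[, c(1, 3)])
  expect_equal(fwd$box, cfg$box * c(1, 1 + eta, 1))
})

test_that("rescaling along z is forbidden and FENE breakage is guarded", {
  cfg <- small_bilayer()
  expect_error(rescale_axial(cfg, 0.05, "z"))
  # bonds are nearly parallel to z: lateral strain limits are wide open,
  # so compute the admissible range and violate it deliberately
  rng <- admissible_strain(cfg, "y")
  expect_true(rng[1] < 0, rng[2] > 0)
  expect_error(rescale_axial(cfg, rng[2] * 1.5 + 1, "y"), "admissible")
  # a configuration with a bond stretched along y has a tight limit
  straight <- mem_config(cbind(c(1, 1), c(1, 1.85), c(1, 1)),
                         c("solvent", "solvent"), list(1L, 2L),
                         box = c(10, 10, 10),
                         bonds = rbind(c(1L, 2L)))
  rng2 <- admissible_strain(straight, "y")
  expect_lt(rng2[2], 0.06)   # 0.85 -> below 0.9 means eta < ~0.059
  expect_error(rescale_axial(straight, 0.1, "y"), "admissible")
})

test_that("a triangular spring lattice relaxes to Poisson ratio ~ 1/3", {
  net <- make_triangular_network(n = 10, spacing = 1, stiffness = 100)
  # static oracle: affine minimisation, independent of the MC engine
  expect_equal(static_poisson(net, 0.02), 1 / 3, tolerance = 0.02)
  # the full protocol (NPT MC, strain, constrained relaxation)
  st <- mc_settings(sweeps = 0, displacement_max = 0.05,
                    box_move_max = 0.001, fixed_axes = "z",
                    move_axes = c("x", "y"), seed = 31, sample_every = 5)
  pr <- measure_poisson(net, phase_point("custom", P = 0, T = 0.1),
                        eta = 0.05, axis = "y", relax_sweeps = 9000,
                        anneal_sweeps = 0, burn_in = 4000,
                        baseline_sweeps = 3000, settings = st)
  expect_identical(pr$nu$pair, "nu_xy")
  expect_equal(pr$nu$estimate, 1 / 3, tolerance = 0.05 * 3)
  expect_lt(abs(pr$nu$estimate - 1 / 3), 0.05)
})

test_that("the zero-strain control is consistent with zero", {
  net <- make_triangular_network(n = 8, spacing = 1, stiffness = 100)
  st <- mc_settings(sweeps = 0, displacement_max = 0.05,
                    box_move_max = 0.001, fixed_axes = "z",
                    move_axes = c("x", "y"), seed = 17, sample_every = 5)
  pr <- measure_poisson(net, phase_point("custom", P = 0, T = 0.1),
                        eta = 0, axis = "y", relax_sweeps = 6000,
                        anneal_sweeps = 0, burn_in = 2500,
                        baseline_sweeps = 2500, settings = st)
  expect_lt(abs(pr$nu$estimate), 4 * pr$nu$stderr + 1e-4)
})

test_that("the strained axis stays fixed for the whole relaxation", {
  net <- make_triangular_network(n = 6, spacing = 1, stiffness = 100)
  st <- mc_settings(sweeps = 0, displacement_max = 0.05,
                    box_move_max = 0.001, fixed_axes = "z",
                    move_axes = c("x", "y"), seed = 23, sample_every = 1)
  pr <- measure_poisson(net, phase_point("custom", P = 0, T = 0.1),
                        eta = 0.05, axis = "y", relax_sweeps = 600,
                        anneal_sweeps = 0, burn_in = 300,
                        baseline_sweeps = 400, settings = st)
  expect_equal(pr$plateau_window, c(301, 600))
  expect_identical(nrow(pr$traces), 600L)
  expect_equal(pr$series$Ly, rep((1 + 0.05) * pr$L0[["y"]], 600),
               tolerance = 1e-12)
})
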