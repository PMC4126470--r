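test_that("zero sweeps returns the input configuration unchanged", {
  gas <- make_phantom_gas(20, box = c(4, 4, 4), seed = 1)
  out <- run_mc(gas, phase_point("fluid"), mc_settings(sweeps = 0, seed = 1))
  expect_identical(out$config$positions, gas$positions)
  expect_identical(out$config$box, gas$box)
  expect_identical(nrow(out$series), 0L)
})

test_that("trajectories are bit-identical under the same seed", {
  cfg <- small_bilayer(jitter = 0)
  st <- mc_settings(sweeps = 30, seed = 123, sample_every = 5)
  a <- run_mc(cfg, phase_point("fluid"), st)
  b <- run_mc(cfg, phase_point("fluid"), st)
  expect_identical(a$config$positions, b$config$positions)
  expect_identical(a$series, b$series)
  c <- run_mc(cfg, phase_point("fluid"),
              mc_settings(sweeps = 30, seed = 124, sample_every = 5))
  expect_false(identical(a$config$positions, c$config$positions))
})

test_that("fixing all axes reduces the chain to canonical sampling", {
  gas <- make_phantom_gas(30, box = c(4, 4, 4), seed = 2)
  out <- run_mc(gas, phase_point("fluid"),
                mc_settings(sweeps = 50, fixed_axes = c("x", "y", "z"),
                            seed = 5))
  expect_identical(out$n_box_moves, 0)
  expect_identical(out$config$box, gas$box)
})

test_that("running energy bookkeeping matches recomputation from scratch", {
  cfg <- small_bilayer()
  st <- mc_settings(sweeps = 200, seed = 11, box_move_max = 0.005)
  out <- run_mc(cfg, phase_point("fluid"), st)
  expect_equal(out$energy, as.numeric(total_energy(out$config)),
               tolerance = 1e-6)
  # and for a system with box moves plus a toy network (harmonic bonds)
  net <- make_triangular_network(n = 6, jitter = 0.02, seed = 3)
  st2 <- mc_settings(sweeps = 300, displacement_max = 0.05,
                     box_move_max = 0.002, fixed_axes = "z",
                     move_axes = c("x", "y"), seed = 12)
  out2 <- run_mc(net, phase_point("custom", P = 0, T = 0.1), st2)
  expect_equal(out2$energy, as.numeric(total_energy(out2$config)),
               tolerance = 1e-6)
})

test_that("the barostat reproduces the ideal-gas equation of state", {
  # phantom beads have no interactions: <V> = N T / P exactly for the
  # ln-V move with the N ln(V'/V) Jacobian weight
  n <- 100; P <- 1; T <- 1.3
  gas <- make_phantom_gas(n, box = c(5, 5, 5), seed = 4)
  st <- mc_settings(sweeps = 6000, displacement_max = 0.5,
                    box_move_max = 0.02, seed = 21, sample_every = 2)
  out <- run_mc(gas, phase_point("custom", P = P, T = T), st)
  v <- out$series$volume[out$series$sweep > 2000]
  expect_equal(mean(v), n * T / P, tolerance = 0.08)
})

test_that("equilibrate_phase composes build and run at the phase point", {
  ph <- phase_point("fluid")
  out0 <- equilibrate_phase(c(2, 2), ph, sweeps = 0, seed = 3,
                            solvent_density = 0, solvent_pad = 2)
  built <- build_bilayer(2, 2, ph, solvent_density = 0, solvent_pad = 2,
                         seed = 3)
  expect_identical(out0$config$positions, built$positions)
  out <- equilibrate_phase(c(2, 2), ph, sweeps = 40, seed = 3,
                           descriptor_every = 20,
                           solvent_density = 0, solvent_pad = 2)
  expect_identical(nrow(out$descriptors), 2L)
  expect_identical(max(out$series$sweep), 40)
})
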