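test_that("built bilayers have the documented size and geometry", {
  cfg <- build_bilayer(12, 24, phase_point("fluid"), solvent_density = 0,
                       solvent_pad = 2, seed = 1)
  lip <- Filter(function(m) length(m) == 7, cfg$molecules)
  expect_length(lip, 576)                      # 12 x 24 per leaflet, 2 leaflets
  expect_identical(sum(cfg$kinds != "solvent"), 4032L)
  # straight-chain construction: every bond at r0, every angle zero
  expect_equal(bond_lengths(cfg), rep(0.7, nrow(cfg$bonds)), tolerance = 1e-12)
  d <- membrane_descriptors(cfg)
  expect_equal(d$order_parameter, 1)
  expect_equal(d$chain_length_mean, 4.2, tolerance = 1e-12)  # 6 * r0
  expect_equal(d$area_per_lipid, 1.68, tolerance = 1e-12)
})

test_that("solvent fills the box at the requested density without overlaps", {
  ph <- phase_point("fluid")
  cfg <- build_bilayer(4, 4, ph, seed = 3)
  n_solv <- sum(cfg$kinds == "solvent")
  expect_gt(n_solv, 0)
  # default density is the ideal-gas value P/T of the phase
  vol_slab <- cfg$box[1] * cfg$box[2] * 2 * 6
  expect_equal(n_solv, round(ph$P / ph$T * vol_slab), tolerance = 1)
  # construction promises no active pair below 0.8 sigma, so the energy is
  # finite and FENE-clean
  expect_true(is.finite(as.numeric(total_energy(cfg))))
  expect_error(build_bilayer(4, 4, ph, area_per_lipid_init = 0.5),
               "packing infeasible")
})

test_that("building is deterministic and descriptors are shift-invariant", {
  a <- build_bilayer(3, 4, phase_point("gel"), seed = 7)
  b <- build_bilayer(3, 4, phase_point("gel"), seed = 7)
  expect_identical(a$positions, b$positions)
  expect_identical(a$box, b$box)
  d0 <- membrane_descriptors(a)
  shifted <- a
  shifted$positions[, 3] <- (shifted$positions[, 3] + 2.5) %% a$box[3]
  d1 <- membrane_descriptors(shifted)
  expect_equal(d1$thickness, d0$thickness, tolerance = 1e-9)
  expect_equal(d1$order_parameter, d0$order_parameter, tolerance = 1e-12)
})

test_that("interdigitated construction interpenetrates the leaflets", {
  cfg <- build_bilayer(4, 4, phase_point("interdigitated"), seed = 2)
  d <- membrane_descriptors(cfg)
  expect_equal(d$order_parameter, 1)
  # heads closer together than the straight two-leaflet stack
  ref <- membrane_descriptors(build_bilayer(4, 4, phase_point("fluid"),
                                            seed = 2))
  expect_lt(d$thickness, ref$thickness)
  expect_true(is.finite(as.numeric(total_energy(cfg))))
})

test_that("phase presets carry the published state points", {
  g <- phase_point("gel")
  f <- phase_point("fluid")
  i <- phase_point("interdigitated")
  expect_equal(c(g$P, g$T, g$T_anneal), c(2, 1.08, 1.2))
  expect_equal(c(f$P, f$T, f$T_anneal), c(1, 1.3, 1.4))
  expect_equal(c(i$P, i$T, i$T_anneal), c(0.5, 1.16, 1.3))
  expect_error(phase_point("custom"), "needs P and T")
})
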