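test_that("FENE bond energy matches its closed form and domain", {
  ff <- forcefield_params()
  expect_identical(fene_energy(0.7, ff), 0)
  # frozen high-precision evaluation at r = 0.8: -2 * log(0.75)
  expect_equal(fene_energy(0.8, ff), 0.575364144903562, tolerance = 1e-12)
  # divergence approaching the maximal extension
  expect_gt(fene_energy(0.9 - 1e-8, ff), 30)
  expect_error(fene_energy(0.9, ff), "FENE domain")
  expect_error(fene_energy(0.49, ff), "FENE domain")
  # symmetric about r0 and strictly convex on a grid
  dr <- seq(0.005, 0.19, by = 0.005)
  expect_equal(fene_energy(0.7 + dr, ff), fene_energy(0.7 - dr, ff))
  grid <- fene_energy(seq(0.52, 0.88, by = 0.01), ff)
  expect_true(all(diff(diff(grid)) > 0))
})

test_that("bond-angle energy is nu_ba * (1 - cos theta)", {
  ff <- forcefield_params()
  expect_identical(bond_angle_energy(0, ff), 0)
  expect_equal(bond_angle_energy(pi, ff), 9.4)
  expect_equal(bond_angle_energy(pi / 2, ff), 4.7)
  # monotone on [0, pi]; round-off beyond the clamp is harmless
  th <- seq(0, pi, length.out = 50)
  expect_true(all(diff(bond_angle_energy(th, ff)) > 0))
  expect_equal(bond_angle_energy(pi + 1e-9, ff), 9.4, tolerance = 1e-6)
})

test_that("soft-core pair energy is shifted, cut off, and zero for phantom pairs", {
  ff <- forcefield_params()
  # frozen evaluation: V_LJ(1) - V_LJ(2) for the tail-tail pair
  expect_equal(soft_core_energy(1, c("tail", "tail"), ff),
               -0.968994140625, tolerance = 1e-12)
  expect_identical(soft_core_energy(2, c("tail", "tail"), ff), 0)
  expect_identical(soft_core_energy(1.05, c("head", "tail"), ff), 0)
  expect_identical(soft_core_energy(0.5, c("solvent", "solvent"), ff),
                   rep(0, 1))
  # continuity at the cutoff for every active pair
  pt <- default_pair_table()
  for (r in which(pt$active)) {
    kinds <- c(pt$kind1[r], pt$kind2[r])
    rc <- pt$rc_mult[r] * pt$sigma[r]
    below <- soft_core_energy(rc - 1e-8, kinds, ff)
    expect_lt(abs(below), 1e-6)
    expect_identical(soft_core_energy(rc + 1e-8, kinds, ff), 0)
    expect_identical(soft_core_energy(rc, kinds, ff), 0)  # theta(0) = 0
  }
  # short-cutoff pairs are purely repulsive
  r <- seq(0.7, 1.0999, by = 0.01)
  expect_true(all(soft_core_energy(r, c("head", "head"), ff) > 0))
})

test_that("total energy agrees with a brute-force evaluation", {
  ff <- forcefield_params()
  # a single solvent bead has no active interactions
  gas1 <- make_phantom_gas(1, box = c(5, 5, 5), seed = 1)
  expect_identical(as.numeric(total_energy(gas1, ff)), 0)
  # one straight isolated lipid: only intramolecular second-and-further
  # neighbour soft-core terms survive
  z <- 10 - 0.7 * (0:6)
  lip <- mem_config(cbind(5, 5, z), c("head", rep("tail", 6)), list(1:7),
                    box = c(20, 20, 20))
  expect_equal(as.numeric(total_energy(lip, ff)), brute_energy(lip, ff),
               tolerance = 1e-10)
  # a perturbed multi-lipid patch, against the same oracle
  cfg <- small_bilayer()
  expect_equal(as.numeric(total_energy(cfg, ff)), brute_energy(cfg, ff),
               tolerance = 1e-9)
})

test_that("energy is invariant under rigid translation and box-vector shifts", {
  ff <- forcefield_params()
  cfg <- small_bilayer()
  e0 <- as.numeric(total_energy(cfg, ff))
  shifted <- cfg
  shifted$positions <- sweep(shifted$positions, 2, c(1.23, -0.71, 4.05), "+")
  expect_equal(as.numeric(total_energy(shifted, ff)), e0, tolerance = 1e-9)
  pbc <- cfg
  pbc$positions[5, ] <- pbc$positions[5, ] + cfg$box * c(2, -1, 3)
  expect_equal(as.numeric(total_energy(pbc, ff)), e0, tolerance = 1e-9)
})

test_that("incremental move energies match full recomputation", {
  ff <- forcefield_params()
  cfg <- small_bilayer()
  # null move and unit rescale are exactly zero
  expect_identical(delta_energy(cfg, list(type = "displace", bead = 3,
                                          new = cfg$positions[3, ]), ff), 0)
  expect_equal(delta_energy(cfg, list(type = "rescale", axis = "x",
                                      factor = 1), ff), 0)
  set.seed(99)
  e0 <- as.numeric(total_energy(cfg, ff))
  for (trial in 1:300) {
    i <- sample(nrow(cfg$positions), 1)
    new <- cfg$positions[i, ] + runif(3, -0.05, 0.05)
    dU <- delta_energy(cfg, list(type = "displace", bead = i, new = new), ff)
    after <- cfg
    after$positions[i, ] <- new
    expect_equal(dU, as.numeric(total_energy(after, ff)) - e0,
                 tolerance = 1e-9)
  }
})

test_that("the pair table enforces model invariants", {
  pt <- default_pair_table()
  bad <- pt
  bad$active[bad$kind1 == "solvent" & bad$kind2 == "solvent"] <- TRUE
  expect_error(forcefield_params(pair_table = bad), "phantom")
  expect_error(forcefield_params(nu_fene = -1))
})
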