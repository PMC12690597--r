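test_that("WCA pair energy matches the piecewise form and its shift", {
  p <- forcefield_params()
  # unshifted printed form
  expect_equal(wca_energy(1, p, shifted = FALSE), 0)
  expect_equal(wca_energy(0.9, p, shifted = FALSE), 4 * (0.9^-12 - 0.9^-6))
  expect_equal(wca_energy(0.9, p, shifted = FALSE), 6.6361190, tolerance = 1e-6)
  # zero beyond the cutoff either way
  expect_equal(wca_energy(1.2, p, shifted = FALSE), 0)
  expect_equal(wca_energy(1.2, p, shifted = TRUE), 0)
  expect_equal(wca_energy(2^(1 / 6) + 1e-12, p), 0)
  # shifted form is continuous at the cutoff and +1 at the LJ zero
  expect_equal(wca_energy(2^(1 / 6) - 1e-9, p, shifted = TRUE), 0,
               tolerance = 1e-6)
  expect_equal(wca_energy(1, p, shifted = TRUE), 1)
  expect_error(wca_energy(0, p), "positive")
  expect_error(wca_energy(-1, p), "positive")
})

test_that("harmonic bond energy is quadratic and symmetric about sigma", {
  p <- forcefield_params()
  expect_equal(bond_energy(1, p), 0)
  expect_equal(bond_energy(1.1, p), 25)
  expect_equal(bond_energy(0.9, p), 25)
  expect_error(bond_energy(-0.1, p), "non-negative")
})

test_that("Coulomb pair energy equals l_b q_i q_j / r in thermal units", {
  u <- reduced_units()
  lb <- u$bjerrum_length
  expect_equal(coulomb_pair_energy(lb, 1, 1, u), 1)
  expect_equal(coulomb_pair_energy(lb, 1, -1, u), -1)
  expect_equal(coulomb_pair_energy(2 * lb, 1, 1, u), 0.5)
  expect_error(coulomb_pair_energy(0, 1, 1, u), "positive")
})

test_that("unit bookkeeping maps reduced units onto physical constants", {
  u <- reduced_units()
  expect_equal(physical_bjerrum_nm(u), 1.168 * 0.6)
  expect_equal(reference_temperature_K(1), 120.27236, tolerance = 1e-6)
  expect_equal(coulomb_prefactor_kJ_mol_nm(), 138.935458, tolerance = 1e-8)
  expect_equal(effective_dielectric(u), 138.935458 / 1.168, tolerance = 1e-6)
  # definitional identity tau^2 epsilon = m sigma^2 (reduced: sigma = 1)
  expect_equal(u$tau^2 * u$epsilon, u$mass)
})

test_that("total energy and forces vanish for trivial configurations", {
  u <- reduced_units(); p <- forcefield_params()
  # two neutral beads beyond the WCA cutoff, no bond
  st <- free_bead_state(rbind(c(5, 5, 5), c(7, 5, 5)), c(0, 0), box_edge = 20)
  ef <- total_energy_forces(st, p, u)
  expect_equal(ef$energy, 0)
  expect_equal(max(abs(ef$forces)), 0)
  # isolated bonded dimer at the rest length, zero charges: the unshifted
  # WCA cancels exactly at r = sigma and the bond term is at its minimum
  dim2 <- chain_state(2, charge = 0, box_edge = 20)
  ef2 <- total_energy_forces(dim2, forcefield_params(wca_shift = FALSE), u)
  expect_equal(ef2$energy, 0)
})

test_that("non-neutral systems are rejected by the periodic solver", {
  u <- reduced_units()
  st <- free_bead_state(rbind(c(1, 1, 1), c(3, 3, 3)), c(1, 0), box_edge = 10)
  expect_error(total_energy_forces(st, units = u), "neutral")
})

test_that("forces are the negative gradient of the energy (finite differences)", {
  u <- reduced_units()
  p <- forcefield_params(coulomb_realspace_cutoff = 2.9,
                         coulomb_accuracy = 1e-7)
  set.seed(42)
  for (rep in 1:2) {
    n <- 10
    pos <- matrix(runif(3 * n, 0, 6), n, 3)
    q <- rep(c(1, -1), n / 2)
    st <- system_state(pos, NULL, q,
                       rep(c("COUNTERION", "COION"), n / 2),
                       c(1L, 1L, 1L, rep(-1L, n - 3)),
                       rbind(c(1L, 2L), c(2L, 3L)), 6)
    ef <- total_energy_forces(st, p, u)
    fd <- fd_forces(st, p, u, beads = 1:4)
    rel <- abs(fd - ef$forces[1:4, ]) / pmax(abs(ef$forces[1:4, ]), 1)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("energy is invariant under rigid translation and periodic image shifts", {
  u <- reduced_units()
  p <- forcefield_params(coulomb_realspace_cutoff = 3.9,
                         coulomb_accuracy = 1e-6)
  set.seed(1)
  n <- 8
  pos <- matrix(runif(3 * n, 0, 8), n, 3)
  q <- rep(c(1, -1), 4)
  st <- free_bead_state(pos, q, box_edge = 8)
  e0 <- total_energy_forces(st, p, u)$energy
  st2 <- st; st2$positions <- wrap_positions(sweep(pos, 2, -c(1.3, -2.1, 0.7)), 8)
  expect_equal(total_energy_forces(st2, p, u)$energy, e0, tolerance = 1e-9)
  st3 <- st; st3$positions[3, 1] <- st3$positions[3, 1] + 8
  st3$positions <- wrap_positions(st3$positions, 8)
  expect_equal(total_energy_forces(st3, p, u)$energy, e0, tolerance = 1e-12)
})

test_that("Ewald electrostatics reproduce the rock-salt lattice sum", {
  u <- reduced_units()
  st <- rocksalt_state(a = 1)
  ef <- total_energy_forces(st, forcefield_params(coulomb_accuracy = 1e-8), u)
  # Madelung constant 1.747565 per ion pair, 4 pairs, nn distance 1
  expect_equal(ef$coulomb, -4 * 1.747565 * u$bjerrum_length,
               tolerance = 1e-6)
  # and a neutral ion pair against the direct (shell-by-shell) lattice sum
  pair <- free_bead_state(rbind(c(2, 2, 2), c(4.5, 2, 2)), c(1, -1),
                          box_edge = 7)
  e_ewald <- total_energy_forces(pair,
                                 forcefield_params(coulomb_realspace_cutoff = 3.4,
                                                   coulomb_accuracy = 1e-8),
                                 u)$coulomb
  e_direct <- polyplexmd:::direct_coulomb_sum_cpp(pair$positions, pair$charge,
                                                  7, u$bjerrum_length, 40L)
  # the cube-truncated direct sum converges to the vacuum boundary; Ewald
  # uses conducting (tinfoil) boundaries -- they differ by the dipole
  # surface term 2 pi l_b |M|^2 / (3V)
  M <- colSums(pair$positions * pair$charge)
  surface <- 2 * pi * u$bjerrum_length * sum(M^2) / (3 * 7^3)
  expect_equal(e_ewald, e_direct - surface, tolerance = 1e-3)
})
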