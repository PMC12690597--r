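fake_np <- function(n_rna, n_pei = 0) {
  np <- list(member_chain_ids = integer(0), member_bead_indices = integer(0),
             attached_ion_indices = integer(0), n_rna_chains = n_rna,
             n_pei_chains = n_pei)
  class(np) <- "nanoparticle"
  np
}

test_that("the order parameter counts RNA-containing NPs per RNA chain", {
  # 8 chains in one NP
  expect_equal(n_nps_star_series(list(list(fake_np(8))), 8)$n_nps_star, 1 / 8)
  # 8 single-RNA NPs
  expect_equal(n_nps_star_series(list(replicate(8, fake_np(1),
                                                simplify = FALSE)),
                                 8)$n_nps_star, 1)
  # 4 NPs of 2 chains each
  expect_equal(n_nps_star_series(list(replicate(4, fake_np(2),
                                                simplify = FALSE)),
                                 8)$n_nps_star, 0.5)
  # free polycation clusters are excluded
  expect_equal(n_nps_star_series(list(list(fake_np(2), fake_np(0, 3))),
                                 2)$n_nps_star, 0.5)
  expect_error(n_nps_star_series(list(list(fake_np(1))), 0), "RNA")
})

test_that("free-energy profiles: flat for uniform occupancy, Gaussian oracle", {
  # uniform occupancy: F identically zero after the shift
  series <- rep(c(1, 2, 3, 4) / 8, each = 50)
  prof <- free_energy_profile(series, 8)
  expect_true(all(abs(prof$F) < 1e-12))
  # discretized Gaussian: fitted minimum and curvature recovered
  set.seed(99)
  mu <- 0.5; s <- 0.1
  draws <- rnorm(1e5, mu, s)
  prof2 <- free_energy_profile(draws, 32)
  expect_lt(abs(prof2$minimum - mu), 1 / 32)
  expect_equal(prof2$curvature, 1 / s^2, tolerance = 0.1)
  # argmin is stable under adding a constant count to every bin
  base_counts <- table(round(draws * 32))
  flat <- rep(as.numeric(names(base_counts)) / 32, 40)
  prof3 <- free_energy_profile(c(draws, flat), 32)
  expect_lt(abs(prof3$minimum - mu), 1 / 32)
  # single occupied bin: fit unavailable, minimum = the bin
  prof4 <- free_energy_profile(rep(0.25, 10), 4)
  expect_null(prof4$fit)
  expect_equal(prof4$minimum, 0.25)
})

test_that("profiles are invariant under stride subsampling (statistically)", {
  set.seed(7)
  draws <- rnorm(2e4, 0.6, 0.12)
  p_all <- free_energy_profile(draws, 16)
  p_sub <- free_energy_profile(draws[seq(1, length(draws), by = 4)], 16)
  expect_lt(abs(p_all$minimum - p_sub$minimum), 1 / 16)
})

test_that("the excess-ratio transform has its fixed points and collapse identity", {
  # alpha N/P = 1 is a fixed point at any concentration
  expect_equal(np_star_transform(1, c_rna = 0.3, c_ref_rna = 0.7)$alpha_np_star, 1)
  expect_equal(np_star_transform(1, c_rna = 5, c_ref_rna = 0.7)$alpha_np_star, 1)
  # at the reference concentration the transform is the identity
  expect_equal(np_star_transform(6, 0.7, 0.7, np_ratio = 12)$np_star, 12)
  # worked example: N/P = 5 at half the reference, isoelectric N/P 1.7
  expect_equal(np_star_transform(2.5, 0.5, 1, np_ratio = 5,
                                 np_iso = 1.7)$np_star, 3.35)
  expect_error(np_star_transform(1, 1, 0), "c_ref_rna")
  # collapse: equal (alpha N/P - 1) * c_rna means equal alpha N/P*
  set.seed(11)
  for (k in 1:25) {
    prod <- runif(1, -0.5, 5)
    c1 <- runif(1, 0.1, 2); c2 <- runif(1, 0.1, 2); cref <- runif(1, 0.5, 2)
    a1 <- prod / c1 + 1; a2 <- prod / c2 + 1
    expect_equal(np_star_transform(a1, c1, cref)$alpha_np_star,
                 np_star_transform(a2, c2, cref)$alpha_np_star,
                 tolerance = 1e-12)
  }
})

test_that("the two starred-ratio transforms agree at N/P_iso = 1/alpha", {
  set.seed(5)
  for (k in 1:10) {
    np_iso <- runif(1, 1.2, 3)
    np <- runif(1, 0.5, 20)
    c_rna <- runif(1, 0.2, 2)
    tr <- np_star_transform(np / np_iso, c_rna, 1, np_ratio = np,
                            np_iso = np_iso)
    expect_equal(tr$np_star / np_iso, tr$alpha_np_star, tolerance = 1e-12)
  }
})

test_that("polycation binding condenses a stretched RNA chain (R_h drops)", {
  u <- reduced_units()
  pp <- forcefield_params(coulomb_realspace_cutoff = 11.7,
                          coulomb_accuracy = 5e-4)
  run_rh <- function(n_pei, seed) {
    sp <- system_spec(1, 30, n_pei, 10, 24, seed = seed)
    st <- build_random_system(sp)
    st <- relax_and_equilibrate(st, pp, u, integrator_params(seed = seed + 1),
                                equil_steps = 5000L)
    tr <- integrate_md(st, integrator_params(n_steps = 40000L,
                                             trajectory_stride = 2000L,
                                             seed = seed + 2), pp, u)
    met <- np_metrics_table(tr, frames = seq(n_frames(tr) %/% 2,
                                             n_frames(tr)))
    mean(met$r_h[met$n_rna_chains > 0])
  }
  rh_bare <- run_rh(0, 900)      # stretched polyelectrolyte
  rh_iso <- run_rh(3, 910)       # neutralized, collapsed complex
  expect_lt(rh_iso, rh_bare)
})

test_that("condition summaries average the equilibrated half across replicates", {
  set.seed(3)
  mk <- function(rep_id, shift) {
    data.frame(condition = "alphaNP=1", replicate = rep_id,
               frame = 1:20,
               r_h = c(rep(99, 10), rep(5 + shift, 10)),   # first half ignored
               kappa2 = 0.2 + shift, charge = 1, n_nps_star = 0.5)
  }
  m <- rbind(mk(1, 0), mk(2, 0.2))
  s <- sweep_summary(m)
  rh <- s[s$metric == "r_h", ]
  expect_equal(rh$mean, 5.1)
  expect_equal(rh$sd, sd(c(5, 5.2)))
  expect_equal(rh$n_replicates, 2)
  expect_false(rh$single_replicate)
  # permuting replicate order changes nothing
  s2 <- sweep_summary(rbind(mk(2, 0.2), mk(1, 0)))
  expect_equal(s2, s)
  # single replicate: sd 0, flagged
  s1 <- sweep_summary(mk(1, 0))
  expect_true(all(s1$sd == 0))
  expect_true(all(s1$single_replicate))
})
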