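test_that("chains link into nanoparticles by the distance cutoff, transitively", {
  # two 4-bead chains with closest approach set by the y offset
  close2 <- multi_chain_state(rbind(c(5, 5, 5), c(5, 8.4, 5)))
  expect_length(find_nanoparticles(close2), 1)
  far2 <- multi_chain_state(rbind(c(5, 5, 5), c(5, 8.6, 5)))
  expect_length(find_nanoparticles(far2), 2)
  # A-B at 3, B-C at 3, A-C at 6: one NP of three chains
  abc <- multi_chain_state(rbind(c(5, 5, 5), c(5, 8, 5), c(5, 11, 5)))
  nps <- find_nanoparticles(abc)
  expect_length(nps, 1)
  expect_equal(sort(nps[[1]]$member_chain_ids), 1:3)
  # an isolated chain is a single-chain NP
  solo <- chain_state(5, charge = 0)
  expect_length(find_nanoparticles(solo), 1)
})

test_that("clustering is invariant under rigid translation across the box", {
  st <- multi_chain_state(rbind(c(5, 5, 5), c(5, 8, 5), c(5, 20, 5)))
  base <- find_nanoparticles(st)
  st2 <- st
  st2$positions <- wrap_positions(sweep(st$positions, 2, -c(47, 49, 48.5)), 50)
  shifted <- find_nanoparticles(st2)
  expect_equal(lapply(shifted, `[[`, "member_chain_ids"),
               lapply(base, `[[`, "member_chain_ids"))
})

test_that("ions attach to nanoparticles within the shell cutoff", {
  ch <- chain_state(4, origin = c(10, 10, 10), charge = -1, species = "RNA")
  pos <- rbind(ch$positions, c(10, 12, 10), c(10, 30, 10))
  st <- system_state(pos, NULL, c(ch$charge, 1, 1),
                     c(ch$species, "COUNTERION", "COUNTERION"),
                     c(ch$chain_id, -1L, -1L), ch$bonds, 50)
  # ion bookkeeping is off-neutral here on purpose; clustering only
  nps <- find_nanoparticles(st)
  expect_length(nps, 1)
  expect_equal(nps[[1]]$attached_ion_indices, 5L)
})

test_that("shape anisotropy hits its exact limits", {
  # collinear equally spaced beads: kappa^2 = 1
  line <- chain_state(10, charge = 0)
  gm <- gyration_metrics(as_np(line), line)
  expect_equal(gm$kappa2, 1)
  expect_equal(gm$eigvals[2], 0)
  # cube vertices: fully degenerate tensor, kappa^2 = 0
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) + 5
  stc <- system_state(cube, NULL, rep(0, 8), rep("RNA", 8), rep(1L, 8),
                      matrix(integer(0), 0, 2), 50)
  gmc <- gyration_metrics(as_np(stc, 1:8), stc)
  expect_equal(gmc$kappa2, 0)
  expect_equal(gmc$eigvals[1], gmc$eigvals[3])
})

test_that("radius of gyration: two beads give d/2; tensor route equals direct sum", {
  two <- chain_state(2, spacing = 3, charge = 0)
  gm <- gyration_metrics(as_np(two), two)
  expect_equal(gm$r_g, 1.5)
  expect_equal(sum(gm$eigvals), gm$r_g^2)
  # random coils: eigenvalue route == direct route to machine precision
  set.seed(4)
  for (k in 1:5) {
    sp <- system_spec(1, 20, 0, 1, 30, seed = k)
    st <- build_random_system(sp)
    np <- as_np(st, which(st$species == "RNA"))
    expect_equal(gyration_metrics(np, st)$r_g,
                 radius_of_gyration_direct(np, st), tolerance = 1e-12)
  }
  # single bead: r_g = 0, kappa2 flagged undefined
  one <- chain_state(1, charge = 0)
  gm1 <- gyration_metrics(as_np(one), one)
  expect_equal(gm1$r_g, 0)
  expect_true(is.na(gm1$kappa2))
})

test_that("cluster unwrapping restores metrics across periodic boundaries", {
  # straight 6-bead chain crossing the x boundary of a 20-box
  pos <- cbind(c(17, 18, 19, 0, 1, 2), 5, 5)
  st <- system_state(pos, NULL, rep(0, 6), rep("RNA", 6), rep(1L, 6),
                     cbind(1:5, 2:6), 20)
  gm <- gyration_metrics(as_np(st), st)
  ref <- chain_state(6, charge = 0)
  gm_ref <- gyration_metrics(as_np(ref), ref)
  expect_equal(gm$r_g, gm_ref$r_g, tolerance = 1e-12)
  expect_equal(gm$kappa2, 1)
})

test_that("Kirkwood hydrodynamic radius closed forms and homogeneity", {
  two <- free_bead_state(rbind(c(5, 5, 5), c(5, 5, 8)), c(0, 0))
  st2 <- system_state(two$positions, NULL, c(0, 0), c("RNA", "RNA"),
                      c(1L, 1L), matrix(integer(0), 0, 2), 50)
  expect_equal(hydrodynamic_radius(as_np(st2, 1:2), st2), 3)
  # equilateral triangle of side d: R_h = d
  d <- 2.5
  tri <- rbind(c(0, 0, 0), c(d, 0, 0), c(d / 2, d * sqrt(3) / 2, 0)) + 10
  st3 <- system_state(tri, NULL, rep(0, 3), rep("RNA", 3), rep(1L, 3),
                      matrix(integer(0), 0, 2), 50)
  expect_equal(hydrodynamic_radius(as_np(st3, 1:3), st3), d)
  # scaling all coordinates scales R_h linearly
  st4 <- st3; st4$positions <- (tri - 10) * 1.7 + 10
  expect_equal(hydrodynamic_radius(as_np(st4, 1:3), st4), 1.7 * d)
  # attached ions are part of the sum
  sti <- system_state(rbind(c(5, 5, 5), c(5, 5, 7)), NULL, c(-1, 1),
                      c("RNA", "COUNTERION"), c(1L, -1L),
                      matrix(integer(0), 0, 2), 50)
  expect_equal(hydrodynamic_radius(as_np(sti, 1L, 2L), sti), 2)
  # under two items: flagged
  expect_true(is.na(hydrodynamic_radius(as_np(sti, 1L), sti)))
})

test_that("nanoparticle charge decomposes by species and sums correctly", {
  # one RNA 4-chain with all four counterions attached: neutral NP
  ch <- chain_state(4, origin = c(10, 10, 10))
  ions <- sweep(ch$positions, 2, c(0, 1.2, 0), `+`)
  st <- system_state(rbind(ch$positions, ions), NULL,
                     c(rep(-1, 4), rep(1, 4)),
                     c(rep("RNA", 4), rep("COUNTERION", 4)),
                     c(rep(1L, 4), rep(-1L, 4)), ch$bonds, 50)
  nps <- find_nanoparticles(st)
  qc <- np_charge(nps[[1]], st)
  expect_equal(qc$total, 0)
  expect_equal(qc$parts[["polymer"]], -4)
  expect_equal(qc$parts[["counterion"]], 4)
  expect_equal(sum(qc$parts), qc$total)
  # isoelectric NP with no attached ions: zero total
  iso <- multi_chain_state(rbind(c(5, 5, 5), c(5, 6.5, 5)), len = 3)
  iso$charge <- c(rep(-1, 3), rep(1, 3))
  iso$species <- c(rep("RNA", 3), rep("PEI", 3))
  qiso <- np_charge(find_nanoparticles(iso)[[1]], iso)
  expect_equal(qiso$total, 0)
})

test_that("zeta-potential matches closed forms for radial charge profiles", {
  u <- reduced_units(); lb <- u$bjerrum_length
  # net charge Q = +2 concentrated near the centre: zeta = lb Q (1/R_h - 1/50)
  pos <- rbind(c(30, 30, 30), c(30.5, 30, 30))
  st <- system_state(pos, NULL, c(1, 1), c("PEI", "PEI"), c(1L, 1L),
                     cbind(1L, 2L), 60)
  np <- as_np(st, 1:2)
  rh <- hydrodynamic_radius(np, st)
  expect_equal(rh, 0.5)
  expect_equal(zeta_potential(np, st, u),
               lb * 2 * (1 / rh - 1 / 50), tolerance = 1e-10)
  # adding a +/- pair at one radius from the NP's centre of mass
  # (30.25, 30, 30) changes nothing
  pos2 <- rbind(pos, c(36.25, 30, 30), c(24.25, 30, 30))
  st2 <- system_state(pos2, NULL, c(1, 1, 1, -1),
                      c("PEI", "PEI", "COUNTERION", "COION"),
                      c(1L, 1L, -1L, -1L), cbind(1L, 2L), 60)
  expect_equal(zeta_potential(as_np(st2, 1:2), st2, u),
               zeta_potential(np, st, u), tolerance = 1e-10)
  # Gauss check: a neutralizing shell outside R_h cancels beyond its radius
  oct <- rbind(c(6, 0, 0), c(-6, 0, 0), c(0, 6, 0), c(0, -6, 0),
               c(0, 0, 6), c(0, 0, -6))
  pos3 <- rbind(pos, sweep(oct, 2, c(30.25, 30, 30), `+`))
  st3 <- system_state(pos3, NULL, c(1, 1, rep(-1, 6) * c(1, 1, 1, 1, 1, -1)),
                      c("PEI", "PEI", rep("COION", 6)),
                      c(1L, 1L, rep(-1L, 6)), cbind(1L, 2L), 60)
  # -2 net on shell would overshoot; use exactly neutralizing -2 shell:
  st3$charge <- c(1, 1, -1, -1, 0, 0, 0, 0)
  z3 <- zeta_potential(as_np(st3, 1:2), st3, u)
  # closed form: +2 from R_h to 50 minus 2 from 6 to 50
  expect_equal(z3, lb * (2 * (1 / 0.5 - 1 / 50) - 2 * (1 / 6 - 1 / 50)),
               tolerance = 1e-10)
  # all charge inside R_h summing to zero: zeta = 0
  stz <- system_state(rbind(c(30, 30, 30), c(30.4, 30, 30)), NULL, c(1, -1),
                      c("PEI", "RNA"), c(1L, 2L), matrix(integer(0), 0, 2), 60)
  npz <- list(member_chain_ids = 1:2, member_bead_indices = 1:2,
              attached_ion_indices = integer(0), n_rna_chains = 1,
              n_pei_chains = 1)
  expect_equal(zeta_potential(npz, stz, u, r_h = 1), 0)
  expect_error(zeta_potential(npz, stz, u, r_h = 60), "cutoff")
})

test_that("Manning fraction counts bound counterions per backbone charge", {
  u <- reduced_units()
  ch <- chain_state(5, origin = c(10, 10, 10))
  # no ions at all: zero
  expect_equal(manning_fraction(ch, units = u), 0)
  # every bead paired with a contact counterion: full neutralization
  ions <- sweep(ch$positions, 2, c(0, 1, 0), `+`)
  st <- system_state(rbind(ch$positions, ions), NULL,
                     c(rep(-1, 5), rep(1, 5)),
                     c(rep("RNA", 5), rep("COUNTERION", 5)),
                     c(rep(1L, 5), rep(-1L, 5)), ch$bonds, 50)
  expect_equal(manning_fraction(st, units = u), 1)
  # distant ions do not count
  far <- system_state(rbind(ch$positions, c(40, 40, 40)), NULL,
                      c(rep(-1, 5), 1),
                      c(rep("RNA", 5), "COUNTERION"),
                      c(rep(1L, 5), -1L), ch$bonds, 50)
  expect_equal(manning_fraction(far, units = u), 0)
  expect_equal(manning_theory(u), 1 - 1 / 1.168)
})
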