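test_that("bilinear bond force follows its three branches", {
  expect_equal(bond_force(14.00), 0)
  # just below the hyperelastic knee: first-branch stiffness
  expect_equal(bond_force(18.20 - 1e-9), 17.13 * 4.2, tolerance = 1e-6)
  # at and beyond the knee: second branch
  expect_equal(bond_force(18.20), 97.66 * 4.2)
  expect_equal(bond_force(20.5), 97.66 * 6.5)
  # beyond rupture: no force
  expect_equal(bond_force(22.0), 0)
  expect_equal(bond_force(16, broken = TRUE), 0)
})

test_that("bond energy is the continuous antiderivative of the force", {
  expect_equal(bond_energy(14.00), 0)
  expect_equal(bond_energy(18.20), 0.5 * 17.13 * 4.2^2)  # 151.09
  # continuity across the knee
  expect_equal(bond_energy(18.2 - 1e-9), bond_energy(18.2 + 1e-9),
               tolerance = 1e-5)
  # constant beyond rupture
  expect_equal(bond_energy(21.5), bond_energy(25))
  # numerical derivative equals the force magnitude off the breakpoints
  for (r in c(15.1, 17.9, 19.3, 20.7)) {
    h <- 1e-6
    dnum <- (bond_energy(r + h) - bond_energy(r - h)) / (2 * h)
    expect_equal(dnum, bond_force(r), tolerance = 1e-6 * max(1, bond_force(r)))
  }
})

test_that("harmonic angle energy uses radians for the deviation", {
  expect_equal(angle_energy(172, 172), 0)
  # 0.1 rad deviation
  expect_equal(angle_energy(172 + 0.1 * 180 / pi, 172), 0.5 * 14.98 * 0.01,
               tolerance = 1e-9)
})

test_that("Lennard-Jones pair classes reproduce their roots and minima", {
  expect_equal(pair_energy(14.72, "collagen")$energy, 0, tolerance = 1e-12)
  # minimum of the mineral class at 2^(1/6) sigma is -epsilon_HAP
  pm <- pair_energy(2^(1 / 6) * 10.28, "mineral")
  expect_equal(pm$energy, -106.7, tolerance = 1e-9)
  expect_equal(pm$force, 0, tolerance = 1e-9)
  # truncation: identically zero beyond the class cutoff
  expect_equal(pair_energy(13.86, "mineral")$energy, 0)
  expect_equal(pair_energy(36.9, "collagen")$force, 0)
})

test_that("compiled evaluation matches the brute-force all-pairs oracle", {
  for (seed in c(1, 2, 3)) {
    m <- random_test_model(n_chains = 3, beads_per_chain = 12, n_mineral = 10,
                           seed = seed)
    fr <- compute_forces(m)
    expect_equal(fr$energy$E_total, oracle_energy(m), tolerance = 1e-10)
  }
  # larger system, still <= 200 beads
  m <- random_test_model(n_chains = 8, beads_per_chain = 18, n_mineral = 30,
                         seed = 9)
  expect_lte(nrow(m$beads), 200)
  fr <- compute_forces(m)
  expect_equal(fr$energy$E_total, oracle_energy(m), tolerance = 1e-10)
})

test_that("analytic forces equal the negative numerical energy gradient", {
  m <- random_test_model(n_chains = 2, beads_per_chain = 6, n_mineral = 4,
                         seed = 11)
  fr <- compute_forces(m)
  fnum <- oracle_forces(m)
  scale <- max(abs(fnum), 1)
  expect_lt(max(abs(fr$forces - fnum)) / scale, 1e-6)
})

test_that("Newton's third law and translation invariance hold", {
  m <- random_test_model(seed = 21)
  fr <- compute_forces(m)
  net <- colSums(fr$forces)
  expect_lt(max(abs(net)) / max(abs(fr$forces)), 1e-8)
  # translate (with axial wrap) and re-evaluate
  m2 <- m
  m2$beads$x <- (m2$beads$x + 57.3) %% m2$box$length[1]
  m2$beads$y <- m2$beads$y + 11.1
  fr2 <- compute_forces(m2)
  expect_equal(fr2$energy$E_total, fr$energy$E_total, tolerance = 1e-10)
})

test_that("bonded dimer at rest length with exclusions has zero energy", {
  d <- minfibril:::mcf_defaults()
  beads <- tibble::tibble(id = 1:2, species = "collagen", molecule = 1L,
                          axial_index = 1:2, x = c(50, 64), y = 0, z = 0,
                          vx = 0, vy = 0, vz = 0, mass = d$mass_collagen)
  bonds <- tibble::tibble(i = 1L, j = 2L, kind = "backbone", r0 = d$r0,
                          r1 = d$r1, r_break = d$r_break, kT0 = d$kT0,
                          kT1 = d$kT1, broken = FALSE)
  m <- fibril_model(beads, bonds,
                    angles = tibble::tibble(i = integer(), j = integer(),
                                            k = integer(), phi0 = numeric(),
                                            kB = numeric()),
                    box = list(length = c(200, 200, 200),
                               periodic = c(TRUE, FALSE, FALSE), L_ref = 200),
                    registry = list(volume_factor = 100))
  fr <- compute_forces(m)
  expect_equal(fr$energy$E_total, 0)
  expect_equal(max(abs(fr$forces)), 0)
})

test_that("bond rupture is irreversible and flags are monotone", {
  m <- build_fixture("single_molecule", n_beads = 5)
  # stretch one bond past r_break
  m$beads$x[5] <- m$beads$x[4] + 21.5
  fr <- compute_forces(m, allow_breaking = TRUE)
  expect_identical(fr$newly_broken, 4L)
  m2 <- fr$model
  expect_true(m2$bonds$broken[4])
  # re-shorten: the bond stays broken and carries no force or energy
  m2$beads$x[5] <- m2$beads$x[4] + 14
  fr2 <- compute_forces(m2, allow_breaking = TRUE)
  expect_true(fr2$model$bonds$broken[4])
  expect_length(fr2$newly_broken, 0)
  # a ruptured bond stores no energy even back at its rest length
  expect_equal(fr2$energy$E_bond, 0, tolerance = 1e-9)
  expect_equal(bond_energy(14, broken = TRUE), 0)
})

test_that("overlapping beads trip the guard distance error", {
  m <- random_test_model(n_chains = 1, beads_per_chain = 4, n_mineral = 1,
                         seed = 2)
  m$beads$x[5] <- m$beads$x[1] + 0.1
  m$beads$y[5] <- m$beads$y[1]
  m$beads$z[5] <- m$beads$z[1]
  expect_error(compute_forces(m), "guard distance")
})

test_that("cutoff-shifted pair energies remove the truncation step", {
  m <- random_test_model(seed = 31)
  e_plain <- compute_forces(m)$energy$E_total
  e_shift <- compute_forces(m, shift_lj = TRUE)$energy$E_total
  expect_equal(e_shift, oracle_energy(m, shift_lj = TRUE), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(e_plain, e_shift)))
})
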