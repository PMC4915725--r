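test_that("virial stress of a single stretched bond matches the closed form", {
  d <- minfibril:::mcf_defaults()
  r <- 16  # stretched: F = kT0 (r - r0)
  beads <- tibble::tibble(id = 1:2, species = "collagen", molecule = 1L,
                          axial_index = 1:2, x = c(100, 100 + r), y = 0, z = 0,
                          vx = 0, vy = 0, vz = 0, mass = d$mass_collagen)
  bonds <- tibble::tibble(i = 1L, j = 2L, kind = "backbone", r0 = d$r0,
                          r1 = d$r1, r_break = d$r_break, kT0 = d$kT0,
                          kT1 = d$kT1, broken = FALSE)
  vf <- 150
  m <- fibril_model(beads, bonds,
                    angles = tibble::tibble(i = integer(), j = integer(),
                                            k = integer(), phi0 = numeric(),
                                            kB = numeric()),
                    box = list(length = c(300, 200, 200),
                               periodic = c(TRUE, FALSE, FALSE), L_ref = 300),
                    registry = list(volume_factor = vf))
  s <- virial_stress(m)
  expected <- stress_to_GPa(d$kT0 * (r - d$r0) * r / (vf * 300))
  expect_equal(s, expected, tolerance = 1e-12)
})

test_that("non-interacting motionless beads carry zero stress", {
  d <- minfibril:::mcf_defaults()
  beads <- tibble::tibble(id = 1:3, species = "mineral",
                          molecule = NA_integer_, axial_index = NA_integer_,
                          x = c(50, 100, 150), y = 0, z = 0,
                          vx = 0, vy = 0, vz = 0, mass = d$mass_mineral)
  m <- fibril_model(beads,
                    bonds = tibble::tibble(i = integer(), j = integer(),
                                           kind = character(), r0 = numeric(),
                                           r1 = numeric(), r_break = numeric(),
                                           kT0 = numeric(), kT1 = numeric(),
                                           broken = logical()),
                    angles = tibble::tibble(i = integer(), j = integer(),
                                            k = integer(), phi0 = numeric(),
                                            kB = numeric()),
                    box = list(length = c(300, 200, 200),
                               periodic = c(TRUE, FALSE, FALSE), L_ref = 300),
                    registry = list(volume_factor = 100))
  expect_equal(virial_stress(m), 0)
})

test_that("per-bead virial sum equals the subset decomposition", {
  m <- random_test_model(seed = 17)
  fr <- compute_forces(m)
  coll <- m$beads$species == "collagen"
  expect_equal(sum(fr$wxx), sum(fr$wxx[coll]) + sum(fr$wxx[!coll]),
               tolerance = 1e-10)
  # observables are pure functions: repeated evaluation is identical
  expect_identical(virial_stress(m), virial_stress(m))
})

test_that("molecular strain tracks uniform bond stretch", {
  sm <- build_fixture("single_molecule", n_beads = 20)
  ms0 <- molecular_strain(sm)
  expect_equal(ms0$mean_strain, 0, tolerance = 1e-12)
  # uniform 10% stretch of every bond
  sm2 <- sm
  sm2$beads$x <- sm2$beads$x[1] + (sm2$beads$x - sm2$beads$x[1]) * 1.1
  sm2$box$length[1] <- sm2$box$length[1] * 1.2
  ms <- molecular_strain(sm2)
  expect_equal(ms$mean_strain, 0.10, tolerance = 1e-9)
})

test_that("gap/overlap profile counts five segments of each kind", {
  m <- cached_default_model()
  prof <- gap_overlap_profile(m)
  expect_identical(prof$n_gap_segments, 5L)
  expect_identical(prof$n_overlap_segments, 5L)
  expect_false(prof$degenerate)
  expect_equal(prof$normalized_overlap_length, 1, tolerance = 0.2)
  # a bin wider than the gap is rejected
  expect_error(gap_overlap_profile(m, bin_width = 400), "bin width")
})

test_that("an unstaggered rod degenerates the classification", {
  mp <- build_fixture("molecule_pair", n_beads = 40)
  prof <- gap_overlap_profile(mp, bin_width = 14)
  expect_true(prof$degenerate)
})

test_that("shrunken molecule spans reduce the normalized overlap length", {
  m <- mini_model(0)
  # contract every molecule towards its own centre (termini relaxation);
  # unwrap across the periodic seam before scaling
  b <- m$beads
  Lx <- m$box$length[1]
  for (mol in unique(b$molecule)) {
    sel <- which(b$molecule == mol)
    sel <- sel[order(b$axial_index[sel])]
    xs <- b$x[sel]
    steps <- diff(xs); steps <- steps - Lx * round(steps / Lx)
    xun <- xs[1] + cumsum(c(0, steps))
    ctr <- mean(xun)
    b$x[sel] <- (ctr + (xun - ctr) * 0.85) %% Lx
  }
  m2 <- m; m2$beads <- b
  p2 <- gap_overlap_profile(m2)
  expect_lt(p2$normalized_overlap_length,
            gap_overlap_profile(m)$normalized_overlap_length)
  expect_lt(p2$normalized_overlap_length, 1)
})

test_that("class-filtered energy sums isolate the mineral interactions", {
  m0 <- mini_model(0)
  s0 <- interaction_energy_sums(m0)
  expect_equal(s0$E_coll_mineral, 0)
  expect_equal(s0$E_mineral_mineral, 0)

  # two mineral beads at the Lennard-Jones minimum
  d <- minfibril:::mcf_defaults()
  beads <- tibble::tibble(id = 1:2, species = "mineral",
                          molecule = NA_integer_, axial_index = NA_integer_,
                          x = c(100, 100 + 2^(1 / 6) * 10.28), y = 0, z = 0,
                          vx = 0, vy = 0, vz = 0, mass = d$mass_mineral)
  m <- fibril_model(beads,
                    bonds = tibble::tibble(i = integer(), j = integer(),
                                           kind = character(), r0 = numeric(),
                                           r1 = numeric(), r_break = numeric(),
                                           kT0 = numeric(), kT1 = numeric(),
                                           broken = logical()),
                    angles = tibble::tibble(i = integer(), j = integer(),
                                            k = integer(), phi0 = numeric(),
                                            kB = numeric()),
                    box = list(length = c(300, 200, 200),
                               periodic = c(TRUE, FALSE, FALSE), L_ref = 300),
                    registry = list(volume_factor = 100))
  s <- interaction_energy_sums(m)
  expect_equal(s$E_mineral_mineral, -106.7, tolerance = 1e-9)
  # matches the brute-force class-filtered loop
  expect_equal(s$E_mineral_mineral, oracle_energy(m), tolerance = 1e-10)
})

test_that("broken-bond counts are monotone over a rupturing trajectory", {
  tt <- single_molecule_pull()
  series <- count_broken_bonds(tt$samples)
  expect_true(all(diff(series$n_broken) >= 0))
  expect_gte(max(series$n_broken), 1)
})

test_that("a run without rupture reports an all-zero series", {
  eq <- mini_equilibrated(0)
  series <- count_broken_bonds(eq$report)
  expect_true(all(series$n_broken == 0))
})
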