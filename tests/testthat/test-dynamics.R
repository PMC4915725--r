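test_that("Maxwell-Boltzmann initialization hits the setpoint", {
  m <- cached_default_model()  # 28305 beads: tight equipartition statistics
  m <- initialize_velocities(m, T = 300, seed = 12)
  expect_lt(abs(kinetic_temperature(m) - 300) / 300, 0.02)
  # centre-of-mass momentum removed
  p <- c(sum(m$beads$mass * m$beads$vx), sum(m$beads$mass * m$beads$vy),
         sum(m$beads$mass * m$beads$vz))
  expect_lt(max(abs(p)), 1e-6)
  # T = 0: all zero; determinism: same seed, same draw
  m0 <- initialize_velocities(m, T = 0, seed = 12)
  expect_true(all(m0$beads$vx == 0 & m0$beads$vy == 0 & m0$beads$vz == 0))
  m1 <- initialize_velocities(m, T = 300, seed = 12)
  m2 <- initialize_velocities(m, T = 300, seed = 12)
  expect_identical(m1$beads$vx, m2$beads$vx)
})

test_that("NVE integration conserves energy on an unbreakable dimer", {
  d <- minfibril:::mcf_defaults()
  beads <- tibble::tibble(id = 1:2, species = "collagen", molecule = 1L,
                          axial_index = 1:2, x = c(100, 100 + 15.5),
                          y = c(0, 0.3), z = 0, vx = 0, vy = 0, vz = 0,
                          mass = d$mass_collagen)
  bonds <- tibble::tibble(i = 1L, j = 2L, kind = "backbone", r0 = d$r0,
                          r1 = 1e5, r_break = 1e6, kT0 = d$kT0, kT1 = d$kT1,
                          broken = FALSE)
  m <- fibril_model(beads, bonds,
                    angles = tibble::tibble(i = integer(), j = integer(),
                                            k = integer(), phi0 = numeric(),
                                            kB = numeric()),
                    box = list(length = c(400, 200, 200),
                               periodic = c(TRUE, FALSE, FALSE), L_ref = 400),
                    registry = list(volume_factor = 100))
  st <- engine_state(m, engine_config(seed = 1))
  r <- minfibril:::run_engine(st, 10000, thermostat = FALSE,
                              sample_every = 100)
  etot <- r$samples$kinetic + r$samples$E_bond + r$samples$E_lj_coll
  # secular drift: symplectic integrators show a bounded energy oscillation
  # of order (omega dt)^2 but no systematic trend
  n <- length(etot)
  head_m <- mean(etot[1:ceiling(n / 10)])
  tail_m <- mean(etot[(n - ceiling(n / 10) + 1):n])
  drift <- abs(tail_m - head_m) / max(abs(head_m), max(etot) - min(etot))
  expect_lt(drift, 1e-4)
})

test_that("harmonic dimer oscillates at the closed-form period", {
  d <- minfibril:::mcf_defaults()
  beads <- tibble::tibble(id = 1:2, species = "collagen", molecule = 1L,
                          axial_index = 1:2, x = c(100, 114.5), y = 0, z = 0,
                          vx = 0, vy = 0, vz = 0, mass = d$mass_collagen)
  bonds <- tibble::tibble(i = 1L, j = 2L, kind = "backbone", r0 = d$r0,
                          r1 = 1e5, r_break = 1e6, kT0 = d$kT0, kT1 = d$kT1,
                          broken = FALSE)
  m <- fibril_model(beads, bonds,
                    angles = tibble::tibble(i = integer(), j = integer(),
                                            k = integer(), phi0 = numeric(),
                                            kB = numeric()),
                    box = list(length = c(400, 200, 200),
                               periodic = c(TRUE, FALSE, FALSE), L_ref = 400),
                    registry = list(volume_factor = 100))
  st <- engine_state(m, engine_config(timestep = 2, seed = 1))
  r <- minfibril:::run_engine(st, 6000, thermostat = FALSE, sample_every = 1)
  # period from E_bond minima spacing (twice per cycle)
  x <- r$samples$E_bond
  mins <- which(diff(sign(diff(x))) > 0) + 1
  period_fs <- 2 * mean(diff(r$samples$time_fs[mins]))
  u <- mcf_units()
  mu_red <- d$mass_collagen / 2
  omega <- sqrt(d$kT0 * u$acc_factor / mu_red)  # rad/fs
  expect_lt(abs(period_fs - 2 * pi / omega) / (2 * pi / omega), 0.01)
})

test_that("zero forces and velocities leave positions unchanged", {
  m <- build_fixture("single_molecule", n_beads = 8)  # chain at rest length
  st <- engine_state(m, engine_config(seed = 1))
  st2 <- step_engine(st, 50, thermostat = FALSE)
  expect_equal(st2$model$beads$x, m$beads$x, tolerance = 1e-12)
  expect_equal(st2$model$beads$y, m$beads$y, tolerance = 1e-12)
})

test_that("trajectories are deterministic given config and seed", {
  mf <- mini_model(15)
  st <- engine_state(mf, engine_config(seed = 99))
  st <- initialize_velocities(st, 300, seed = 99)
  r1 <- minfibril:::run_engine(st, 2000, thermostat = TRUE, sample_every = 500)
  r2 <- minfibril:::run_engine(st, 2000, thermostat = TRUE, sample_every = 500)
  expect_identical(r1$state$model$beads$x, r2$state$model$beads$x)
  expect_identical(r1$samples, r2$samples)
})

test_that("thermostated runs hold the temperature setpoint", {
  eq <- mini_equilibrated(0)
  rep <- eq$report
  late <- rep$temperature[rep$step >= 0.75 * max(rep$step)]
  expect_lt(abs(mean(late) - 300), 10)
})

test_that("pure collagen fibril shows only marginal contraction", {
  eq <- mini_equilibrated(0)
  expect_lt(abs(eq$contraction_pct), 8)
  expect_true(eq$converged)
})

test_that("mineralized fibril contracts during equilibration", {
  eq <- mini_equilibrated(30)
  expect_gt(eq$contraction_pct, 5)
})

test_that("tensile rate guard rejects unstable rates", {
  mf <- mini_model(15)
  st <- engine_state(mf, engine_config(seed = 1))
  expect_error(run_tensile_test(st, rate = 1e9, max_strain = 0.1),
               "stability bound")
})

test_that("zero pull rate leaves strain at zero", {
  sm <- build_fixture("single_molecule", n_beads = 30, periodic_chain = TRUE)
  st <- engine_state(sm, engine_config(seed = 5))
  st <- initialize_velocities(st, 300, seed = 5)
  res <- minfibril:::run_engine(st, 2000, thermostat = TRUE,
                                pull_rate_m_s = 0, sample_every = 500)
  expect_equal(res$samples$Lx, rep(sm$box$length[1], nrow(res$samples)))
})

test_that("pull rate converts to the documented box extension per step", {
  # 1 m/s = 1e-5 A/fs = 1e-4 A per 10-fs step
  sm <- build_fixture("single_molecule", n_beads = 30, periodic_chain = TRUE)
  st <- engine_state(sm, engine_config(seed = 5))
  res <- minfibril:::run_engine(st, 1000, thermostat = FALSE,
                                pull_rate_m_s = 1, sample_every = 1000)
  dL <- res$samples$Lx[2] - res$samples$Lx[1]
  # multiplicative box updates accumulate ~1e3 rounding ulps
  expect_equal(dL / 1000, 1e-4, tolerance = 1e-6)
})

test_that("single-molecule tension follows the bilinear closed form", {
  tt <- single_molecule_pull()
  cv <- tt$curve
  m1 <- fit_modulus(cv, c(0.05, 0.25))
  m2 <- fit_modulus(cv, c(0.33, 0.46))
  # slope ratio of the two branches: kT1/kT0 = 97.66/17.13 = 5.701
  expect_lt(abs(m2$modulus_gpa / m1$modulus_gpa - 97.66 / 17.13) /
              (97.66 / 17.13), 0.08)
  # rupture near the bond-breaking strain (21 - 14)/14 = 50% (thermal
  # activation breaks the weakest link slightly early)
  iu <- which.max(cv$stress)
  expect_gt(cv$strain[iu], 0.43)
  expect_lt(cv$strain[iu], 0.52)
  # one broken bond ends the percolating chain
  expect_gte(max(tt$samples$n_broken), 1)
})
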