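test_that("default geometry reproduces the reference fibril counts", {
  m <- cached_default_model()
  expect_identical(m$registry$n_molecules, 158L)
  expect_identical(sum(m$beads$species == "collagen"), 28305L)
  expect_identical(nrow(validate_model(m)), 0L)
})

test_that("equilibrium angles form a small discrete set in [164, 180]", {
  m <- cached_default_model()
  phis <- unique(m$angles$phi0)
  expect_lte(length(phis), 13)
  expect_true(all(phis >= 164 & phis <= 180))
  expect_true(all(phis == round(phis)))
})

test_that("angle assignment measures, rounds and clamps", {
  # straight chain: all angles 180
  sm <- build_fixture("single_molecule", n_beads = 6)
  expect_true(all(sm$angles$phi0 == 180))
  # constructed 3-bead triple at 167.4 degrees rounds to 167
  d <- minfibril:::mcf_defaults()
  ang <- 167.4 * pi / 180
  beads <- tibble::tibble(
    id = 1:3, species = "collagen", molecule = 1L, axial_index = 1:3,
    x = c(50, 64, 64 - 14 * cos(ang)), y = c(0, 0, 14 * sin(ang)), z = 0,
    vx = 0, vy = 0, vz = 0, mass = d$mass_collagen)
  m <- fibril_model(
    beads,
    bonds = tibble::tibble(i = 1:2, j = 2:3, kind = "backbone", r0 = d$r0,
                           r1 = d$r1, r_break = d$r_break, kT0 = d$kT0,
                           kT1 = d$kT1, broken = FALSE),
    angles = tibble::tibble(i = integer(), j = integer(), k = integer(),
                            phi0 = numeric(), kB = numeric()),
    box = list(length = c(500, 500, 500), periodic = c(TRUE, FALSE, FALSE),
               L_ref = 500))
  m <- assign_angles(m)
  expect_identical(m$angles$phi0, 167)
})

test_that("builder is deterministic given spec and seed", {
  a <- build_fixture("mini_fibril", diameter_nm = 5, mineral_wt_pct = 15,
                     seed = 4)
  b <- build_fixture("mini_fibril", diameter_nm = 5, mineral_wt_pct = 15,
                     seed = 4)
  expect_identical(a$beads, b$beads)
  expect_identical(a$bonds, b$bonds)
  expect_identical(a$angles, b$angles)
})

test_that("mineralization hits the target weight fraction identity", {
  # closed-form identity at several targets on the mini fibril
  for (w in c(5, 15, 30, 45)) {
    m <- build_fixture("mini_fibril", diameter_nm = 5, mineral_wt_pct = w)
    expect_lt(abs(mineral_wt_pct(m) - w), 0.5)
    n_min <- sum(m$beads$species == "mineral")
    n_coll <- sum(m$beads$species == "collagen")
    w_identity <- 100 * n_min * 1548 / (n_min * 1548 + n_coll * 1324)
    expect_equal(mineral_wt_pct(m), w_identity)
  }
  # target 0: no mineral beads
  m0 <- build_fixture("mini_fibril", diameter_nm = 5, mineral_wt_pct = 0)
  expect_identical(sum(m0$beads$species == "mineral"), 0L)
})

test_that("an unreachable mineral target names the achievable maximum", {
  g <- geometry_spec(diameter_nm = 4, d_period = 335, periods = 2,
                     n_molecules = NULL, total_beads = NULL,
                     crimp_wavelength = NULL)
  expect_error(
    build_fibril(g, mineralization_spec(45, lattice_spacing = 25)),
    "achievable maximum")
})

test_that("low density gives two disjoint mineral clusters per gap region", {
  m <- build_fibril(geometry_spec(), mineralization_spec(5), seed = 1)
  gaps <- m$registry$gaps
  minx <- m$beads$x[m$beads$species == "mineral"]
  for (gi in seq_len(nrow(gaps))) {
    xs <- sort(minx[minx >= gaps$gap_lo[gi] & minx <= gaps$gap_hi[gi]])
    expect_gt(length(xs), 10)
    # largest axial void inside the gap separates the two clusters
    biggest_void <- max(diff(xs))
    expect_gt(biggest_void, 3 * 2^(1 / 6) * 10.28)
    # both sides of the void are populated
    split_at <- which.max(diff(xs))
    expect_gt(split_at, 1)
    expect_lt(split_at, length(xs) - 1)
  }
})

test_that("gap regions hold fewer molecules per cross-section than overlaps", {
  m <- cached_default_model()
  prof <- gap_overlap_profile(m)
  expect_identical(prof$n_gap_segments, 5L)
  expect_identical(prof$n_overlap_segments, 5L)
  po <- prof$profile
  expect_gt(min(po$n_molecules[po$region == "overlap"]),
            max(po$n_molecules[po$region == "gap"]))
})

test_that("axial periodicity: all bond lengths stay near the rest length", {
  m <- cached_default_model()
  bl <- bond_lengths(m)  # includes bonds straddling the seam
  expect_lt(max(abs(bl - 14)), 0.2)
})

test_that("crosslinks join distinct molecules at termini", {
  # isolated single molecule: no partner, warning, zero crosslinks
  sm <- build_fixture("single_molecule", n_beads = 10)
  expect_warning(sm2 <- add_crosslinks(sm, crosslink_spec()), "skipped")
  expect_identical(sum(sm2$bonds$kind == "crosslink"), 0L)

  # adjacent pair: up to 2 per molecule, each inter-molecular
  mp <- build_fixture("molecule_pair", n_beads = 12)
  mp2 <- add_crosslinks(mp, crosslink_spec(search_radius = 16))
  xl <- mp2$bonds[mp2$bonds$kind == "crosslink", ]
  expect_lte(nrow(xl), 4)
  expect_gt(nrow(xl), 0)
  mol_of <- mp2$beads$molecule
  expect_true(all(mol_of[xl$i] != mol_of[xl$j]))

  # mini fibril: at most 2 per molecule in total
  mf <- suppressWarnings(
    build_fixture("mini_fibril", diameter_nm = 5, crosslink = crosslink_spec()))
  n_mol <- mf$registry$n_molecules
  expect_lte(sum(mf$bonds$kind == "crosslink"), 2 * n_mol)
  expect_gt(sum(mf$bonds$kind == "crosslink"), 0)
})

test_that("molecule pair at lattice separation is adhesive", {
  mp <- build_fixture("molecule_pair", n_beads = 30, separation = 14.72 * 1.12)
  fr <- compute_forces(mp)
  expect_lt(fr$energy$E_nonbonded, 0)
  expect_equal(fr$energy$E_nonbonded, oracle_energy(mp), tolerance = 1e-10)
})

test_that("mini fibril with mineral validates and meets tolerance", {
  m <- build_fixture("mini_fibril", diameter_nm = 7, mineral_wt_pct = 25)
  expect_identical(nrow(validate_model(m)), 0L)
  expect_lt(abs(mineral_wt_pct(m) - 25), 0.5)
})
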