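# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the compiled engine: energies come
# from the scalar R force-field functions via an O(N^2) double loop, forces
# from central differences of that energy.

oracle_min_image <- function(dx, lx) dx - lx * round(dx / lx)

# excluded pair set (1-2 bonds, 1-3 angle ends) as a character key set
oracle_exclusions <- function(model) {
  keys <- character(0)
  if (nrow(model$bonds) > 0)
    keys <- c(keys, paste(pmin(model$bonds$i, model$bonds$j),
                          pmax(model$bonds$i, model$bonds$j)))
  if (nrow(model$angles) > 0)
    keys <- c(keys, paste(pmin(model$angles$i, model$angles$k),
                          pmax(model$angles$i, model$angles$k)))
  unique(keys)
}

# total potential energy by direct summation over every bond, angle and
# (non-excluded) pair
oracle_energy <- function(model, shift_lj = FALSE) {
  b <- model$beads
  lx <- model$box$length[1]
  E <- 0
  if (nrow(model$bonds) > 0) {
    for (r in seq_len(nrow(model$bonds))) {
      bd <- model$bonds[r, ]
      dx <- oracle_min_image(b$x[bd$i] - b$x[bd$j], lx)
      d <- sqrt(dx^2 + (b$y[bd$i] - b$y[bd$j])^2 + (b$z[bd$i] - b$z[bd$j])^2)
      E <- E + bond_energy(d, bd$r0, bd$r1, bd$r_break, bd$kT0, bd$kT1,
                           broken = bd$broken)
    }
  }
  if (nrow(model$angles) > 0) {
    for (r in seq_len(nrow(model$angles))) {
      an <- model$angles[r, ]
      v1 <- c(oracle_min_image(b$x[an$i] - b$x[an$j], lx),
              b$y[an$i] - b$y[an$j], b$z[an$i] - b$z[an$j])
      v2 <- c(oracle_min_image(b$x[an$k] - b$x[an$j], lx),
              b$y[an$k] - b$y[an$j], b$z[an$k] - b$z[an$j])
      cosv <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      phi <- acos(max(-1, min(1, cosv))) * 180 / pi
      E <- E + angle_energy(phi, an$phi0, an$kB)
    }
  }
  excl <- oracle_exclusions(model)
  n <- nrow(b)
  cls_of <- function(i, j) {
    if (b$species[i] == b$species[j]) {
      if (b$species[i] == "collagen") "collagen" else "mineral"
    } else "inter"
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (paste(i, j) %in% excl) next
      dx <- oracle_min_image(b$x[i] - b$x[j], lx)
      d <- sqrt(dx^2 + (b$y[i] - b$y[j])^2 + (b$z[i] - b$z[j])^2)
      E <- E + pair_energy(d, cls_of(i, j), model$pair_table,
                           shift = shift_lj)$energy
    }
  }
  E
}

# forces as the negative central-difference gradient of oracle_energy
oracle_forces <- function(model, h = 1e-5) {
  n <- nrow(model$beads)
  f <- matrix(0, n, 3)
  cols <- c("x", "y", "z")
  for (i in seq_len(n)) {
    for (d in 1:3) {
      mp <- model; mp$beads[[cols[d]]][i] <- mp$beads[[cols[d]]][i] + h
      mm <- model; mm$beads[[cols[d]]][i] <- mm$beads[[cols[d]]][i] - h
      f[i, d] <- -(oracle_energy(mp) - oracle_energy(mm)) / (2 * h)
    }
  }
  f
}

# small random but reproducible test system: a few short chains plus
# mineral beads, positions jittered so no symmetry hides sign errors
random_test_model <- function(n_chains = 3, beads_per_chain = 10,
                              n_mineral = 8, seed = 42, jitter = 0.8) {
  set.seed(seed)
  d <- minfibril:::mcf_defaults()
  beads <- list(); bonds <- list(); angles <- list()
  id <- 0
  for (m in seq_len(n_chains)) {
    ids <- id + seq_len(beads_per_chain)
    beads[[m]] <- tibble::tibble(
      id = ids, species = "collagen", molecule = m,
      axial_index = seq_len(beads_per_chain),
      x = 20 + 14 * (seq_len(beads_per_chain) - 1) + rnorm(beads_per_chain, 0, jitter),
      y = 16 * (m - 1) + rnorm(beads_per_chain, 0, jitter),
      z = rnorm(beads_per_chain, 0, jitter),
      vx = 0, vy = 0, vz = 0, mass = d$mass_collagen)
    bonds[[m]] <- tibble::tibble(
      i = ids[-beads_per_chain], j = ids[-1], kind = "backbone",
      r0 = d$r0, r1 = d$r1, r_break = d$r_break, kT0 = d$kT0, kT1 = d$kT1,
      broken = FALSE)
    angles[[m]] <- tibble::tibble(
      i = ids[1:(beads_per_chain - 2)], j = ids[2:(beads_per_chain - 1)],
      k = ids[3:beads_per_chain],
      phi0 = sample(168:180, beads_per_chain - 2, replace = TRUE),
      kB = d$kB_angle)
    id <- id + beads_per_chain
  }
  if (n_mineral > 0) {
    ids <- id + seq_len(n_mineral)
    beads[[n_chains + 1]] <- tibble::tibble(
      id = ids, species = "mineral", molecule = NA_integer_,
      axial_index = NA_integer_,
      x = runif(n_mineral, 30, 120),
      y = runif(n_mineral, 25, 60),
      z = runif(n_mineral, 10, 40),
      vx = 0, vy = 0, vz = 0, mass = d$mass_mineral)
  }
  beads <- dplyr::bind_rows(beads)
  fibril_model(beads, dplyr::bind_rows(bonds), dplyr::bind_rows(angles),
               box = list(length = c(200, 260, 260),
                          periodic = c(TRUE, FALSE, FALSE), L_ref = 200),
               registry = list(n_molecules = n_chains, diameter_nm = 20,
                               volume_factor = pi * 100^2))
}
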