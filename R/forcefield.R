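# Analytic force-field primitives (vectorized R) and the compiled
# whole-model evaluator. The scalar functions are the reference definitions;
# the compiled path is cross-checked against an independent brute-force sum
# in the test suite.

#' Bilinear breakable bond force
#'
#' Piecewise-linear spring: stiffness `kT0` up to the hyperelastic distance
#' `r1`, `kT1` from `r1` to the rupture distance `r_break`, zero beyond.
#' Positive values pull the beads together (restoring force magnitude
#' `k (r - r0)` along the bond).
#'
#' @param r bond length(s) in A, > 0.
#' @param r0,r1,r_break,kT0,kT1 bond parameters (defaults: collagen
#'   backbone).
#' @param broken logical; a broken bond carries zero force.
#' @return force magnitude along the bond in kcal/mol/A.
#' @examples
#' bond_force(18.20)  # 17.13 * 4.2 = 71.946
#' @export
bond_force <- function(r, r0 = 14.00, r1 = 18.20, r_break = 21.00,
                       kT0 = 17.13, kT1 = 97.66, broken = FALSE) {
  stopifnot(all(r > 0))
  f <- ifelse(r < r1, kT0 * (r - r0),
              ifelse(r < r_break, kT1 * (r - r0), 0))
  ifelse(rep_len(broken, length(r)), 0, f)
}

#' Bilinear bond energy
#'
#' Continuous piecewise-quadratic antiderivative of [bond_force()] with
#' \eqn{\Phi(r_0) = 0}; constant beyond `r_break`. A bond flagged broken
#' stores no energy at all (its elastic energy is considered dissipated at
#' rupture).
#' @inheritParams bond_force
#' @return energy in kcal/mol.
#' @export
bond_energy <- function(r, r0 = 14.00, r1 = 18.20, r_break = 21.00,
                        kT0 = 17.13, kT1 = 97.66, broken = FALSE) {
  stopifnot(all(r > 0))
  e1 <- 0.5 * kT0 * (r1 - r0)^2
  seg2 <- function(x) e1 + 0.5 * kT1 * ((x - r0)^2 - (r1 - r0)^2)
  e <- ifelse(r < r1, 0.5 * kT0 * (r - r0)^2,
              ifelse(r < r_break, seg2(r), seg2(r_break)))
  ifelse(rep_len(broken, length(r)), 0, e)
}

#' Harmonic angle energy
#'
#' \eqn{\Phi(\phi) = \tfrac12 k_B (\phi - \phi_0)^2} with the deviation in
#' radians; `phi` and `phi0` are given in degrees.
#' @param phi measured angle(s), degrees in (0, 360).
#' @param phi0 equilibrium angle, degrees.
#' @param kB bending stiffness, kcal/mol/rad^2.
#' @return energy in kcal/mol.
#' @export
angle_energy <- function(phi, phi0 = 180, kB = 14.98) {
  stopifnot(all(phi > 0), all(phi < 360))
  0.5 * kB * ((phi - phi0) * pi / 180)^2
}

#' Truncated Lennard-Jones pair energy and force
#'
#' Standard 12-6 form with per-class parameters, plainly truncated at the
#' cutoff (optionally shifted to zero there).
#' @param r distance(s) in A, > 0.
#' @param class one of `"collagen"`, `"mineral"`, `"inter"`.
#' @param pair_table tibble as from [default_pair_table()].
#' @param shift logical; subtract the cutoff energy.
#' @return tibble with columns `r`, `energy` (kcal/mol) and `force`
#'   (kcal/mol/A, positive = repulsive, \eqn{-dU/dr}).
#' @export
pair_energy <- function(r, class = c("collagen", "mineral", "inter"),
                        pair_table = default_pair_table(), shift = FALSE) {
  class <- match.arg(class)
  stopifnot(all(r > 0))
  p <- pair_table[pair_table$class == class, ]
  sr6 <- (p$sigma / r)^6
  e <- 4 * p$epsilon * (sr6^2 - sr6)
  f <- 24 * p$epsilon * (2 * sr6^2 - sr6) / r
  if (shift) {
    sc6 <- (p$sigma / p$cutoff)^6
    e <- e - 4 * p$epsilon * (sc6^2 - sc6)
  }
  e[r >= p$cutoff] <- 0
  f[r >= p$cutoff] <- 0
  tibble::tibble(r = r, energy = e, force = f)
}

# ---- compiled whole-model evaluation --------------------------------------

species_code <- function(species) ifelse(species == "mineral", 1L, 0L)

# Pack a fibril_model into the flat list the compiled engine consumes.
model_to_sys <- function(model, skin = 2, shift_lj = FALSE) {
  b <- model$beads
  bd <- model$bonds
  an <- model$angles
  pt <- model$pair_table
  ord <- match(c("collagen", "mineral", "inter"), pt$class)
  list(
    pos = cbind(b$x, b$y, b$z),
    vel = cbind(b$vx, b$vy, b$vz),
    species = species_code(b$species),
    mass = b$mass,
    bonds = cbind(bd$i - 1L, bd$j - 1L),
    bond_params = cbind(bd$r0, bd$r1, bd$r_break, bd$kT0, bd$kT1),
    broken = as.integer(bd$broken),
    angles = cbind(an$i - 1L, an$j - 1L, an$k - 1L),
    angle_params = cbind(an$phi0 * pi / 180, an$kB),
    lj = cbind(pt$sigma[ord], pt$epsilon[ord], pt$cutoff[ord]),
    shift_lj = shift_lj,
    box = model$box$length,
    skin = skin
  )
}

#' Evaluate forces, energies and per-bead virials for a model
#'
#' Sums all bond, angle and pair contributions with 1-2 and 1-3 exclusions
#' and the axial minimum-image convention, through the compiled engine and
#' its Verlet neighbour list.
#'
#' @param model a `fibril_model`.
#' @param allow_breaking logical; if `TRUE`, bonds at or beyond `r_break`
#'   are flagged broken in the returned model.
#' @param skin neighbour-list skin in A.
#' @param shift_lj shift pair energies to zero at the cutoff.
#' @return a `force_result` list: `forces` (N x 3, kcal/mol/A), `wxx`
#'   (per-bead tension-positive axial virial, kcal/mol), `energy` (an
#'   energy-breakdown list), `newly_broken` (bond row indices), `model`
#'   (with updated broken flags when `allow_breaking`),
#'   `n_degenerate_angles`.
#' @export
compute_forces <- function(model, allow_breaking = FALSE, skin = 2,
                           shift_lj = FALSE) {
  sys <- model_to_sys(model, skin = skin, shift_lj = shift_lj)
  res <- cpp_compute_forces(sys, allow_breaking = allow_breaking)
  newly <- which(as.logical(res$broken) & !model$bonds$broken)
  out_model <- model
  if (allow_breaking && length(newly) > 0)
    out_model$bonds$broken[newly] <- TRUE
  structure(list(
    forces = res$force,
    wxx = as.numeric(res$wxx),
    energy = energy_breakdown(res),
    newly_broken = newly,
    model = out_model,
    n_degenerate_angles = res$n_degenerate_angles,
    kinetic = res$kinetic
  ), class = "force_result")
}

# Energy breakdown with the additivity structure
# E_total = E_collagen + E_HAP + E_inter;
# E_collagen = E_bond + E_angle + E_nonbonded(coll-coll LJ).
energy_breakdown <- function(res) {
  e_coll <- res$E_bond + res$E_angle + res$E_lj_coll
  list(E_bond = res$E_bond, E_angle = res$E_angle,
       E_nonbonded = res$E_lj_coll,
       E_collagen = e_coll, E_HAP = res$E_lj_min, E_inter = res$E_lj_inter,
       E_total = e_coll + res$E_lj_min + res$E_lj_inter)
}

#' Apply rupture flags from a force evaluation to a model
#'
#' Bond breakage is irreversible: flags are only ever set, never cleared,
#' so the broken count is monotone non-decreasing over a trajectory.
#' @param result a `force_result` from [compute_forces()].
#' @param model the model the result was computed from.
#' @return the model with `bonds$broken` updated.
#' @export
apply_bond_breaking <- function(result, model) {
  if (length(result$newly_broken) > 0)
    model$bonds$broken[result$newly_broken] <- TRUE
  model
}
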