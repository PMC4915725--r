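#' @title Unit system for the mesoscale fibril model
#'
#' @description
#' All internal quantities use the "real"-style molecular unit system:
#' length in Angstrom (\eqn{\text{\AA}}), energy in kcal/mol, mass in amu
#' (g/mol), time in fs, force in kcal/mol/\eqn{\text{\AA}}. Derived
#' conversions are fixed once here and every reported pN or GPa value flows
#' through them:
#' \itemize{
#'   \item force: 1 kcal/mol/A = 69.479 pN
#'   \item stress: 1 kcal/mol/A^3 = 6.9479 GPa (the same constant divided
#'         by 1 A^2 = 1e-20 m^2)
#'   \item acceleration: a[A/fs^2] = F[kcal/mol/A] / m[amu] * 4.184e-4
#' }
#'
#' @return `mcf_units()` returns a named list of the conversion constants.
#' @examples
#' force_to_pN(1)        # 69.479
#' mcf_units()$gpa_per_kcal_mol_A3
#' @export
mcf_units <- function() {
  list(
    length      = "angstrom",
    energy      = "kcal/mol",
    mass        = "amu",
    time        = "fs",
    force       = "kcal/mol/angstrom",
    pn_per_kcal_mol_A  = 69.479,
    gpa_per_kcal_mol_A3 = 6.9479,
    acc_factor  = 4.184e-4,   # (kcal/mol/A)/amu -> A/fs^2
    kB          = 1.987204259e-3, # kcal/mol/K
    A_per_fs_per_m_s = 1e-5   # 1 m/s = 1e-5 A/fs
  )
}

#' Convert a force from kcal/mol/A to piconewton
#'
#' @param f force in kcal/mol/A (finite, any sign); vectorized.
#' @return force in pN: `f * 69.479`.
#' @examples
#' force_to_pN(17.13 * 4.2)  # 4999.21 pN, bilinear bond at the hyperelastic knee
#' @export
force_to_pN <- function(f) {
  stopifnot(is.numeric(f), all(is.finite(f)))
  f * 69.479
}

#' Convert pN back to kcal/mol/A (exact inverse of [force_to_pN()])
#' @param p force in pN; vectorized.
#' @return force in kcal/mol/A.
#' @export
pN_to_force <- function(p) {
  stopifnot(is.numeric(p), all(is.finite(p)))
  p / 69.479
}

#' Convert a stress from kcal/mol/A^3 to GPa
#'
#' Single documented pathway for every GPa value the package reports.
#' @param s stress in kcal/mol/A^3; vectorized.
#' @return stress in GPa: `s * 6.9479`.
#' @export
stress_to_GPa <- function(s) s * 6.9479

#' @rdname stress_to_GPa
#' @param g stress in GPa.
#' @export
GPa_to_stress <- function(g) g / 6.9479

# Default force-field constants (collagen backbone bilinear bond, angle,
# Lennard-Jones classes). Masses: mineral bead 1548 amu; collagen bead
# 1324 amu (the second mesoscale-particle mass row, read as the 14-A
# triple-helix segment). Both configurable through the spec objects.
mcf_defaults <- function() {
  list(
    r0 = 14.00, r1 = 18.20, r_break = 21.00,
    kT0 = 17.13, kT1 = 97.66,
    kB_angle = 14.98,
    mass_collagen = 1324, mass_mineral = 1548,
    lj = list(
      collagen = list(sigma = 14.72, epsilon = 6.87,  cutoff = 2.5 * 14.72),
      mineral  = list(sigma = 10.28, epsilon = 106.7, cutoff = 13.85),
      inter    = list(sigma = 9.88,  epsilon = 137.1, cutoff = 20.00)
    ),
    angle_min = 164, angle_max = 180
  )
}

#' Default Lennard-Jones pair table
#'
#' Three interaction classes: collagen-collagen, mineral-mineral
#' (hydroxyapatite), and collagen-mineral. The collagen-collagen cutoff is
#' not part of the published parameter set; the default 2.5 sigma = 36.8 A
#' captures the full adhesive well and is configurable.
#'
#' @param coll_cutoff collagen-collagen cutoff in A.
#' @return a tibble with columns `class`, `sigma`, `epsilon`, `cutoff`.
#' @export
default_pair_table <- function(coll_cutoff = 2.5 * 14.72) {
  d <- mcf_defaults()$lj
  tibble::tibble(
    class   = c("collagen", "mineral", "inter"),
    sigma   = c(d$collagen$sigma, d$mineral$sigma, d$inter$sigma),
    epsilon = c(d$collagen$epsilon, d$mineral$epsilon, d$inter$epsilon),
    cutoff  = c(coll_cutoff, d$mineral$cutoff, d$inter$cutoff)
  )
}

#' Cross-sectional area convention for a single tropocollagen molecule
#'
#' Used to convert single-molecule axial force into stress (and hence a
#' Young's modulus). Convention: the molecule occupies one cell of a
#' hexagonally packed lattice at the collagen-collagen Lennard-Jones
#' equilibrium spacing \eqn{2^{1/6}\sigma_{coll}}, so
#' \eqn{A = (\sqrt{3}/2)\,(2^{1/6}\sigma_{coll})^2 \approx 236.3} A^2.
#'
#' @param sigma_coll collagen LJ distance parameter in A.
#' @return area in A^2.
#' @export
molecule_cross_section <- function(sigma_coll = 14.72) {
  (sqrt(3) / 2) * (2^(1 / 6) * sigma_coll)^2
}
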