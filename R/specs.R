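#' Geometry specification for a fibril build
#'
#' Defines the quarter-staggered collagen lattice. Defaults reproduce the
#' reference fibril: a 20-nm-diameter cylinder holding 158 molecules whose
#' beads total 28,305, five D-periods (gap + overlap) per periodic box.
#'
#' @param diameter_nm fibril diameter in nm (cylindrical cut of the lattice).
#' @param d_period axial D-period in A (one gap + one overlap).
#' @param periods number of D-periods in the periodic box; the box length is
#'   `periods * d_period`.
#' @param bead_spacing contour distance between consecutive beads of a
#'   molecule, in A (the bond rest length).
#' @param n_molecules target number of molecules inside the cylinder; the
#'   hexagonal lattice constant is calibrated so that the cylindrical cut
#'   keeps exactly this many chains. `NULL` lets the lattice constant
#'   default to the collagen LJ equilibrium spacing with no calibration.
#' @param total_beads target total collagen bead count; per-molecule bead
#'   counts (differing by at most one bead, assigned deterministically) are
#'   calibrated to sum to this. `NULL` sizes every molecule from
#'   `gap_fraction` alone.
#' @param gap_fraction fraction of the D-period occupied by the gap region
#'   (standard collagen value 0.54; overlap = 0.46).
#' @param crimp_ratio target axial-span-to-contour ratio of a molecule,
#'   used to size molecules when `total_beads` is `NULL` (the toe region of
#'   the stress-strain curve spans roughly `1/crimp_ratio - 1`). When
#'   `total_beads` is given, the realized ratio follows from the bead
#'   counts instead.
#' @param crimp_wavelength wavelength in A of the global transverse crimp
#'   field that gives molecules their initial waviness (and hence the set of
#'   equilibrium angles below 180 degrees). `NULL` (default) auto-selects
#'   the wavelength so the maximum bead-to-bead bend stays within the
#'   13-angle discrete set.
#' @param mass_collagen,mass_mineral bead masses in amu.
#' @return a `geometry_spec` list.
#' @export
geometry_spec <- function(diameter_nm = 20, d_period = 670, periods = 5,
                          bead_spacing = 14.00, n_molecules = 158,
                          total_beads = 28305, gap_fraction = 0.54,
                          crimp_ratio = 0.93, crimp_wavelength = NULL,
                          mass_collagen = 1324, mass_mineral = 1548) {
  stopifnot(diameter_nm > 0, d_period > 0, periods >= 1,
            bead_spacing > 0, gap_fraction > 0, gap_fraction < 1,
            crimp_ratio > 0.7, crimp_ratio <= 1,
            is.null(crimp_wavelength) || crimp_wavelength > 4 * bead_spacing,
            mass_collagen > 0, mass_mineral > 0)
  structure(list(
    diameter_nm = diameter_nm, d_period = d_period, periods = periods,
    bead_spacing = bead_spacing, n_molecules = n_molecules,
    total_beads = total_beads, gap_fraction = gap_fraction,
    crimp_ratio = crimp_ratio, crimp_wavelength = crimp_wavelength,
    mass_collagen = mass_collagen, mass_mineral = mass_mineral
  ), class = "geometry_spec")
}

#' Mineralization specification
#'
#' Intrafibrillar mineral is deposited on a close-packed lattice growing
#' from the molecular terminal planes that bound each gap region, clipped to
#' the fibril cylinder, until the target weight fraction is met.
#'
#' @param target_wt_pct target mineral weight percent of the whole model,
#'   in \[0, 45\].
#' @param tolerance_pct absolute tolerance on the achieved weight percent.
#' @param lattice_spacing nearest-neighbour spacing of the mineral lattice
#'   in A; default is the mineral LJ equilibrium distance
#'   \eqn{2^{1/6}\sigma_{HAP}} so freshly built crystals start near
#'   mechanical equilibrium.
#' @param exclusion_radius minimum distance in A allowed between a mineral
#'   site and any collagen bead.
#' @param radial_margin shrink of the placement cylinder radius in A.
#' @return a `mineralization_spec` list.
#' @export
mineralization_spec <- function(target_wt_pct = 0, tolerance_pct = 0.5,
                                lattice_spacing = 2^(1 / 6) * 10.28,
                                exclusion_radius = 9.5,
                                radial_margin = 0) {
  stopifnot(target_wt_pct >= 0, target_wt_pct <= 45,
            tolerance_pct > 0, lattice_spacing > 0, exclusion_radius >= 0)
  structure(list(
    target_wt_pct = target_wt_pct, tolerance_pct = tolerance_pct,
    lattice_spacing = lattice_spacing, exclusion_radius = exclusion_radius,
    radial_margin = radial_margin
  ), class = "mineralization_spec")
}

#' Crosslink specification
#'
#' Covalent-like crosslinks attach molecule end beads to the nearest bead of
#' a neighbouring molecule. "Trivalent" enzymatic crosslinks are realized as
#' one crosslink bond per molecule end (two per molecule by default).
#' Crosslink bond parameters default to the backbone bilinear set with the
#' rupture distance scaled by `r_break_scale` (a free parameter of the
#' model, not part of the published set).
#'
#' @param per_molecule maximum crosslinks per molecule (default 2: one at
#'   each end).
#' @param search_radius partner search radius in A.
#' @param r_break_scale multiplier on the backbone `r_break` for crosslink
#'   bonds.
#' @return a `crosslink_spec` list.
#' @export
crosslink_spec <- function(per_molecule = 2, search_radius = 22,
                           r_break_scale = 1.0) {
  stopifnot(per_molecule >= 0, search_radius > 0, r_break_scale > 0)
  structure(list(per_molecule = per_molecule, search_radius = search_radius,
                 r_break_scale = r_break_scale), class = "crosslink_spec")
}

#' Engine configuration
#'
#' @param timestep integration time step in fs.
#' @param temperature thermostat setpoint in K.
#' @param damping Langevin damping time in fs.
#' @param pull_rate tensile displacement rate in m/s applied to the box
#'   length.
#' @param barostat `"axial"` (Berendsen-style relaxation of the box length
#'   toward zero axial virial stress) or `"off"`.
#' @param barostat_tau barostat relaxation time in fs.
#' @param barostat_modulus stress scale (GPa) used by the Berendsen update;
#'   larger values mean gentler box adjustments.
#' @param neighbor_skin Verlet-list skin in A.
#' @param shift_lj logical; shift pair energies to zero at the cutoff
#'   (default `FALSE`: plain truncation).
#' @param seed integer seed that fully determines the stochastic streams.
#' @return an `engine_config` list.
#' @export
engine_config <- function(timestep = 10, temperature = 300, damping = 1000,
                          pull_rate = 1, barostat = c("axial", "off"),
                          barostat_tau = 5000, barostat_modulus = 5,
                          neighbor_skin = 2, shift_lj = FALSE, seed = 1L) {
  barostat <- match.arg(barostat)
  stopifnot(timestep > 0, temperature >= 0, damping > 0, pull_rate >= 0,
            barostat_tau > 0, barostat_modulus > 0, neighbor_skin > 0)
  structure(list(
    timestep = timestep, temperature = temperature, damping = damping,
    pull_rate = pull_rate, barostat = barostat, barostat_tau = barostat_tau,
    barostat_modulus = barostat_modulus, neighbor_skin = neighbor_skin,
    shift_lj = isTRUE(shift_lj), seed = as.integer(seed)
  ), class = "engine_config")
}

#' @export
print.geometry_spec <- function(x, ...) {
  cat("<geometry_spec> d =", x$diameter_nm, "nm, D =", x$d_period,
      "A x", x$periods, "periods;",
      if (is.null(x$n_molecules)) "uncalibrated lattice"
      else paste0(x$n_molecules, " molecules"),
      if (!is.null(x$total_beads)) paste0(", ", x$total_beads, " beads"),
      "\n")
  invisible(x)
}

#' @export
print.mineralization_spec <- function(x, ...) {
  cat("<mineralization_spec>", x$target_wt_pct, "wt% (+/-",
      x$tolerance_pct, "%), lattice", round(x$lattice_spacing, 2), "A\n")
  invisible(x)
}

#' @export
print.crosslink_spec <- function(x, ...) {
  cat("<crosslink_spec>", x$per_molecule, "per molecule, search radius",
      x$search_radius, "A\n")
  invisible(x)
}

#' @export
print.engine_config <- function(x, ...) {
  cat("<engine_config> dt =", x$timestep, "fs, T =", x$temperature,
      "K, damping", x$damping, "fs, pull", x$pull_rate, "m/s, barostat",
      x$barostat, "\n")
  invisible(x)
}
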