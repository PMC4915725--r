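# Per-frame measurements: virial stress, molecular strain, gap/overlap
# profiling, class-filtered interaction-energy sums, broken-bond series.
# All observables are pure functions of (model, frame).

#' Patch a trajectory frame into a model
#'
#' @param model the `fibril_model` the trajectory was run from.
#' @param frame one element of the `frames` list returned by
#'   [run_tensile_test()] (or [run_engine] drivers).
#' @return the model with the frame's positions, box length and broken
#'   flags.
#' @export
frame_model <- function(model, frame) {
  model$beads$x <- frame$pos[, 1]
  model$beads$y <- frame$pos[, 2]
  model$beads$z <- frame$pos[, 3]
  model$box$length[1] <- frame$Lx
  model$bonds$broken <- as.logical(frame$broken)
  model
}

#' Axial virial stress of a model configuration
#'
#' Tension-positive axial component of the per-bead virial sum divided by
#' the fibril volume \eqn{\pi (d/2)^2 L_{box}} with the diameter held
#' constant (20 nm for the default fibril). The same volume convention is
#' used for subset (mineral-only) stress.
#'
#' @param model a `fibril_model` (with velocities if `kinetic = TRUE`).
#' @param species `NULL` for all beads, or `"mineral"`/`"collagen"` for a
#'   subset stress normalized by the total fibril volume.
#' @param kinetic include the kinetic term of the virial (default `TRUE`).
#' @param diameter_nm override the volume-convention diameter.
#' @return stress in GPa.
#' @export
virial_stress <- function(model, species = NULL, kinetic = TRUE,
                          diameter_nm = NULL) {
  vf <- if (!is.null(diameter_nm)) pi * (diameter_nm * 10 / 2)^2
        else model$registry$volume_factor %||%
          (pi * ((model$registry$diameter_nm %||%
                    stop("virial_stress: no volume convention available")) *
                   10 / 2)^2)
  V <- vf * model$box$length[1]
  if (V <= 0) stop("virial_stress: zero volume")
  fr <- compute_forces(model)
  u <- mcf_units()
  sel <- if (is.null(species)) rep(TRUE, nrow(model$beads))
         else model$beads$species == species
  w <- sum(fr$wxx[sel])
  if (kinetic)
    w <- w - sum(model$beads$mass[sel] * model$beads$vx[sel]^2) / u$acc_factor
  u$gpa_per_kcal_mol_A3 * w / V
}

#' Per-molecule and mean molecular strain
#'
#' Molecular strain is the current contour length (sum of unbroken bond
#' lengths) over the initial contour length, minus one. Molecules whose
#' bonds are all broken are excluded from the mean and counted separately.
#'
#' @param model a `fibril_model` whose registry stores the initial contours.
#' @return a list: `per_molecule` tibble (`molecule`, `strain`,
#'   `n_broken_bonds`), `mean_strain`, `n_molecules_with_breaks`,
#'   `n_fully_broken`, `per_bead` tibble of bead-level bond strain for
#'   visualization.
#' @export
molecular_strain <- function(model) {
  reg <- model$registry
  if (is.null(reg$molecules$contour0))
    stop("molecular_strain: registry lacks initial contour lengths")
  len <- bond_lengths(model)
  bmol <- model$beads$molecule[model$bonds$i]
  backbone <- model$bonds$kind == "backbone"
  ok <- backbone & !model$bonds$broken
  cur <- tapply(ifelse(ok, len, 0), bmol, sum)
  nb <- tapply(model$bonds$broken & backbone, bmol, sum)
  n_bonds <- tapply(backbone, bmol, sum)
  mols <- as.integer(names(cur))
  c0 <- reg$molecules$contour0[match(mols, reg$molecules$molecule)]
  # contour of unbroken bonds vs initial contour of the same bonds:
  # rescale the reference by the surviving bond fraction
  frac <- (n_bonds - nb) / n_bonds
  strain <- ifelse(frac > 0, cur / (c0 * frac) - 1, NA_real_)
  per <- tibble::tibble(molecule = mols, strain = as.numeric(strain),
                        n_broken_bonds = as.integer(nb))
  per_bead <- tibble::tibble(
    bead = model$bonds$i[backbone],
    bond_strain = ifelse(model$bonds$broken[backbone], NA_real_,
                         len[backbone] / model$bonds$r0[backbone] - 1))
  list(per_molecule = per,
       mean_strain = mean(per$strain, na.rm = TRUE),
       n_molecules_with_breaks = sum(per$n_broken_bonds > 0),
       n_fully_broken = sum(is.na(per$strain)),
       per_bead = per_bead)
}

#' Gap/overlap axial profile
#'
#' Bins the axis (bin width one bead spacing, 14 A) and counts distinct
#' molecules present per bin. Bins are classified gap vs overlap against the
#' midpoint of the construction-time gap and overlap molecule counts stored
#' in the registry.
#'
#' @param model a `fibril_model` built by [build_fibril()].
#' @param bin_width axial bin width in A.
#' @return a list: `profile` tibble (`x_lo`, `x_hi`, `n_molecules`,
#'   `region`), `n_gap_segments`, `n_overlap_segments`,
#'   `gap_overlap_ratio` (total gap length / total overlap length),
#'   `overlap_length`, `normalized_overlap_length` (vs construction),
#'   `degenerate` flag when classification collapses.
#' @export
gap_overlap_profile <- function(model, bin_width = 14) {
  reg <- model$registry
  Lx <- model$box$length[1]
  P <- reg$periods %||% 1
  m_p <- reg$span_periods %||% 0
  n_mol <- reg$n_molecules
  gap_len_ref <- (reg$gap_fraction %||% 0.54) * (reg$d_period %||% Lx)
  if (bin_width >= gap_len_ref)
    stop("gap_overlap_profile: bin width ", bin_width,
         " A is not smaller than the gap length ", round(gap_len_ref), " A")
  n_bins <- max(1, floor(Lx / bin_width))
  edges <- seq(0, Lx, length.out = n_bins + 1)
  bead_bin <- pmin(n_bins, 1 + floor((model$beads$x %% Lx) / (Lx / n_bins)))
  coll <- model$beads$species == "collagen"
  counts <- vapply(seq_len(n_bins), function(b)
    length(unique(model$beads$molecule[coll & bead_bin == b])), integer(1))
  # construction-time per-cross-section class counts: m_p (gap) vs m_p + 1
  # (overlap) stagger classes out of P
  thr <- n_mol * (m_p + 0.5) / P
  region <- ifelse(counts >= thr, "overlap", "gap")
  # degenerate when the model has no stagger registry (uniform rod) or the
  # occupied bins all classify alike
  occupied <- counts > 0
  degenerate <- is.null(reg$gaps) ||
    length(unique(region[occupied])) < 2
  prof <- tibble::tibble(x_lo = edges[-length(edges)], x_hi = edges[-1],
                         n_molecules = counts, region = region)
  r <- rle(region)
  # merge the wrap-around segment (periodic axis)
  n_seg <- function(lab) {
    k <- sum(r$values == lab)
    if (length(r$values) > 1 && r$values[1] == r$values[length(r$values)] &&
        r$values[1] == lab) k - 1 else k
  }
  bw <- Lx / n_bins
  overlap_len <- sum(region == "overlap") * bw
  gap_len <- sum(region == "gap") * bw
  overlap_ref <- (1 - (reg$gap_fraction %||% 0.54)) * (reg$d_period %||% Lx) * P
  list(profile = prof,
       n_gap_segments = n_seg("gap"),
       n_overlap_segments = n_seg("overlap"),
       gap_overlap_ratio = if (overlap_len > 0) gap_len / overlap_len else Inf,
       overlap_length = overlap_len,
       normalized_overlap_length = overlap_len / overlap_ref,
       degenerate = degenerate)
}

#' Class-filtered pair interaction energy sums
#'
#' Sums of the pairwise Lennard-Jones energies between collagen-mineral and
#' mineral-mineral bead pairs; slope changes of these sums over strain
#' diagnose the onset of collagen-mineral sliding.
#'
#' @param model a `fibril_model`.
#' @return tibble with `E_coll_mineral` and `E_mineral_mineral` (kcal/mol).
#' @export
interaction_energy_sums <- function(model) {
  fr <- compute_forces(model)
  tibble::tibble(E_coll_mineral = fr$energy$E_inter,
                 E_mineral_mineral = fr$energy$E_HAP)
}

#' Broken-bond series over a trajectory
#'
#' @param frames list of trajectory frames (each with a `broken` vector), or
#'   a samples tibble containing an `n_broken` column.
#' @param model optional `fibril_model` for the molecule-level failure
#'   fraction at the final frame.
#' @return tibble with `step`, `n_broken` and (when `model` is given) the
#'   final `fraction_molecules_broken` as an attribute.
#' @export
count_broken_bonds <- function(frames, model = NULL) {
  if (is.data.frame(frames)) {
    out <- tibble::tibble(step = frames$step, n_broken = frames$n_broken)
  } else {
    out <- tibble::tibble(
      step = vapply(frames, function(f) as.numeric(f$step), numeric(1)),
      n_broken = vapply(frames, function(f) sum(f$broken), numeric(1)))
  }
  if (!is.null(model) && !is.data.frame(frames) && length(frames) > 0) {
    fm <- frame_model(model, frames[[length(frames)]])
    ms <- molecular_strain(fm)
    attr(out, "fraction_molecules_broken") <-
      ms$n_molecules_with_breaks / model$registry$n_molecules
  }
  out
}

#' Stream per-frame observables to a CSV results file
#'
#' @param samples a samples tibble from a run.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_observables_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}
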