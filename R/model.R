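#' Construct a fibril model object
#'
#' The central particle-system container. Beads, bonds and angles are
#' tibbles; the box and registry are plain lists. Positions are in A,
#' velocities in A/fs. Collagen beads belong to exactly one molecule;
#' mineral beads carry `molecule = NA`.
#'
#' @param beads tibble with columns `id` (1-based integer), `species`
#'   ("collagen"/"mineral"), `molecule` (integer or NA), `axial_index`,
#'   `x`, `y`, `z`, `vx`, `vy`, `vz`, `mass`.
#' @param bonds tibble with `i`, `j` (bead ids), `kind`
#'   ("backbone"/"crosslink"), `r0`, `r1`, `r_break`, `kT0`, `kT1`,
#'   `broken` (logical).
#' @param angles tibble with `i`, `j`, `k`, `phi0` (degrees), `kB`.
#' @param pair_table tibble as from [default_pair_table()].
#' @param box list with `length` (3-vector, A), `periodic` (3 logicals; only
#'   the axial x dimension is periodic), `L_ref` (reference axial length).
#' @param registry list of build metadata: molecule table, gap boundaries,
#'   D-period, mineral weight percent, lattice and crimp constants.
#' @return a `fibril_model` object.
#' @export
fibril_model <- function(beads, bonds, angles, pair_table = default_pair_table(),
                         box, registry = list()) {
  beads <- tibble::as_tibble(beads)
  bonds <- tibble::as_tibble(bonds)
  angles <- tibble::as_tibble(angles)
  structure(list(beads = beads, bonds = bonds, angles = angles,
                 pair_table = tibble::as_tibble(pair_table),
                 box = box, registry = registry),
            class = "fibril_model")
}

#' @export
print.fibril_model <- function(x, ...) {
  n_min <- sum(x$beads$species == "mineral")
  cat("<fibril_model> ", nrow(x$beads), " beads (", n_min, " mineral), ",
      nrow(x$bonds), " bonds (", sum(x$bonds$broken), " broken), ",
      nrow(x$angles), " angles\n", sep = "")
  cat("  box: ", paste(signif(x$box$length, 6), collapse = " x "),
      " A, periodic x\n", sep = "")
  if (!is.null(x$registry$n_molecules))
    cat("  ", x$registry$n_molecules, " molecules, D = ",
        x$registry$d_period, " A x ", x$registry$periods,
        ", mineral ", signif(x$registry$mineral_wt_pct, 3), " wt%\n", sep = "")
  invisible(x)
}

#' Achieved mineral weight percent of a model
#' @param model a `fibril_model`.
#' @return weight percent (0 if unmineralized).
#' @export
mineral_wt_pct <- function(model) {
  w <- tapply(model$beads$mass, model$beads$species, sum)
  m_min <- if ("mineral" %in% names(w)) w[["mineral"]] else 0
  100 * m_min / sum(model$beads$mass)
}

# Minimum-image displacement along the periodic x axis.
min_image_dx <- function(dx, lx) dx - lx * round(dx / lx)

# Pairwise displacement vectors (i minus j) with axial minimum image.
bead_delta <- function(model, i, j) {
  b <- model$beads
  dx <- min_image_dx(b$x[i] - b$x[j], model$box$length[1])
  cbind(dx, b$y[i] - b$y[j], b$z[i] - b$z[j])
}

#' Current bond lengths (axial minimum image)
#' @param model a `fibril_model`.
#' @return numeric vector, one length per bond row.
#' @export
bond_lengths <- function(model) {
  d <- bead_delta(model, model$bonds$i, model$bonds$j)
  sqrt(rowSums(d^2))
}

# Angle (degrees) at vertex j for each angle row.
measure_angles <- function(model) {
  a <- model$angles
  v1 <- bead_delta(model, a$i, a$j)
  v2 <- bead_delta(model, a$k, a$j)
  cosv <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

#' Validate a fibril model against its structural invariants
#'
#' Checks bond parameter ordering, angle membership, species masses and
#' molecule membership, box periodicity and lateral vacuum margins. The
#' model is well-formed iff the returned tibble has zero rows.
#'
#' @param model a `fibril_model`.
#' @return tibble with columns `check` and `detail`, one row per violation.
#' @export
validate_model <- function(model) {
  v <- list()
  add <- function(check, detail) v[[length(v) + 1]] <<- tibble::tibble(
    check = check, detail = detail)
  b <- model$beads
  bd <- model$bonds

  if (nrow(bd) > 0) {
    bad <- !(bd$r0 < bd$r1 & bd$r1 < bd$r_break)
    if (any(bad)) add("bond ordering",
      paste("r0 < r1 < r_break violated for", sum(bad), "bond(s)"))
    if (any(bd$kT0 <= 0 | bd$kT1 <= 0))
      add("bond stiffness", "non-positive spring constant")
  }
  if (nrow(model$angles) > 0) {
    d <- mcf_defaults()
    out <- model$angles$phi0 < d$angle_min | model$angles$phi0 > d$angle_max
    if (any(out)) add("angle range",
      paste(sum(out), "angle(s) outside [164, 180] degrees"))
    if (length(unique(model$angles$phi0)) > 13)
      add("angle membership", "more than 13 distinct equilibrium angles")
  }
  is_min <- b$species == "mineral"
  if (any(is_min & !is.na(b$molecule)))
    add("mineral membership", "mineral bead with a molecule id")
  if (any(!is_min & is.na(b$molecule)))
    add("collagen membership", "collagen bead without a molecule id")
  if (any(b$mass <= 0)) add("species mass", "non-positive bead mass")
  pt <- model$pair_table
  if (any(pt$sigma <= 0 | pt$epsilon <= 0 | pt$cutoff <= 0) ||
      any(pt$cutoff < pt$sigma))
    add("pair table", "sigma/epsilon/cutoff must be positive, cutoff >= sigma")
  if (!isTRUE(model$box$periodic[1]) || isTRUE(model$box$periodic[2]) ||
      isTRUE(model$box$periodic[3]))
    add("box periodicity", "box must be periodic along x only")
  # lateral vacuum margin larger than the largest cutoff
  if (nrow(b) > 1) {
    max_cut <- max(pt$cutoff)
    half <- model$box$length[2:3] / 2
    ext <- c(max(abs(b$y)), max(abs(b$z)))
    if (any(half - ext < max_cut))
      add("box margin",
          "lateral vacuum margin smaller than the largest pair cutoff")
  }
  if (nrow(bd) > 0 && any(bd$i == bd$j)) add("bond topology", "self bond")
  if (length(v) == 0)
    tibble::tibble(check = character(), detail = character())
  else dplyr::bind_rows(v)
}
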