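# Fibril geometry construction: quarter-staggered collagen lattice cut to a
# cylinder, global crimp field, in-silico mineralization of the gap regions,
# optional crosslinks, and small deterministic test fixtures.

# ---- cross-section lattice ------------------------------------------------

# Quasi-hexagonal lattice sites as dimensionless radii (units of the lattice
# constant). A fixed fractional offset breaks the lattice point-group
# symmetry so sites cross the cylinder boundary one at a time, which lets the
# lattice constant be calibrated to hold an exact molecule count.
hex_sites <- function(n_shells) {
  j <- seq(-n_shells, n_shells)
  grid <- expand.grid(i = seq(-n_shells, n_shells), j = j)
  # irrational centre offset: site radii are then pairwise distinct, so the
  # cylinder boundary crosses one site at a time during calibration
  u <- grid$i + (grid$j %% 2) / 2 - 1 / pi
  v <- (sqrt(3) / 2) * grid$j - 1 / exp(1)
  tibble::tibble(i = grid$i, j = grid$j, u = u, v = v,
                 rho = sqrt(u^2 + v^2))
}

# Choose the lattice constant so exactly `target` sites fall inside radius R.
# Site radii scale linearly with the lattice constant, so the count is a
# monotone step function and the constant is the midpoint of the bracketing
# step.
calibrate_lattice <- function(R, target, a_nominal = 2^(1 / 6) * 14.72) {
  sites <- hex_sites(max(8, ceiling(2.5 * R / a_nominal)))
  rho <- sort(sites$rho)
  if (target >= length(rho))
    stop("lattice calibration: site pool too small for target count")
  a <- R / ((rho[target] + rho[target + 1]) / 2)
  keep <- sites[sites$rho * a <= R, ]
  stopifnot(nrow(keep) == target)
  list(a = a, sites = keep)
}

lattice_sites <- function(R, n_molecules, a_nominal = 2^(1 / 6) * 14.72) {
  if (is.null(n_molecules)) {
    sites <- hex_sites(max(8, ceiling(2.5 * R / a_nominal)))
    keep <- sites[sites$rho * a_nominal <= R, ]
    list(a = a_nominal, sites = keep)
  } else {
    calibrate_lattice(R, n_molecules, a_nominal)
  }
}

# ---- crimp field ----------------------------------------------------------

# Global transverse displacement field y -> y + A sin(2 pi x / lambda).
# The slope parameter u = A * (2 pi / lambda) sets the axial-span-to-contour
# ratio of a chain whose beads are equally spaced in arc length:
#   ratio(u) = 1 / mean_x sqrt(1 + u^2 cos^2), independent of lambda.
crimp_ratio <- function(u) {
  phi <- seq(0, pi, length.out = 2001)
  1 / mean(sqrt(1 + u^2 * cos(phi)^2))
}

solve_crimp_u <- function(ratio_target) {
  if (ratio_target >= 1 - 1e-9) return(0)
  lo <- crimp_ratio(3)
  if (ratio_target < lo)
    stop("crimp calibration: requested span/contour ratio ", round(ratio_target, 3),
         " below reachable minimum ", round(lo, 3))
  stats::uniroot(function(u) crimp_ratio(u) - ratio_target,
                 c(1e-8, 3), tol = 1e-10)$root
}

# Maximum bend between consecutive bonds is ~ u * k * spacing; cap it at
# 12.5 degrees so measured equilibrium angles round into at most 13 distinct
# integer values in [168, 180] - the model's discrete angle set. The
# wavenumber is snapped to an integer number of waves per box so the
# displacement field is periodic across the axial boundary.
crimp_field <- function(u, spacing, box_length, wavelength = NULL) {
  max_turn <- 12.5 * pi / 180
  if (u <= 1e-9) return(list(u = 0, k = 0, A = 0, n_waves = 0))
  if (is.null(wavelength)) {
    lambda_min <- u * spacing * 2 * pi / max_turn
    n_w <- floor(box_length / lambda_min)
  } else {
    n_w <- round(box_length / wavelength)
  }
  if (n_w < 1)
    stop("crimp field: box too short for one crimp wave at the required ",
         "amplitude; increase the box length or straighten the molecules")
  k <- 2 * pi * n_w / box_length
  list(u = u, k = k, A = u / k, n_waves = n_w)
}

# Arc-length parameterization of the crimped backbone: bead x-positions with
# equal contour spacing along y = A sin(k x).
crimp_arc <- function(field, x_range, dx = 0.25) {
  if (field$k == 0 || field$u == 0) return(NULL)
  x <- seq(x_range[1] - 1, x_range[2] + 1, by = dx)
  g <- sqrt(1 + (field$u * cos(field$k * x))^2)
  s <- c(0, cumsum((g[-1] + g[-length(g)]) / 2 * diff(x)))
  list(x = x, s = s)
}

# x-positions of n beads starting at x0, spaced `spacing` in arc length.
crimp_bead_x <- function(arc, field, x0, n, spacing) {
  if (is.null(arc)) return(x0 + spacing * (seq_len(n) - 1))
  s0 <- stats::approx(arc$x, arc$s, xout = x0)$y
  stats::approx(arc$s, arc$x, xout = s0 + spacing * (seq_len(n) - 1))$y
}

# ---- builder --------------------------------------------------------------

backbone_bond_params <- function() {
  d <- mcf_defaults()
  list(r0 = d$r0, r1 = d$r1, r_break = d$r_break, kT0 = d$kT0, kT1 = d$kT1)
}

#' Build a mineralized collagen fibril model
#'
#' Lays out quarter-staggered tropocollagen chains on a calibrated
#' quasi-hexagonal lattice cut to a cylinder, applies the global crimp
#' field, assigns the discrete equilibrium-angle set, deposits mineral in
#' the gap regions to the target weight fraction and optionally adds
#' crosslinks. Deterministic given the spec and seed.
#'
#' @param geometry a [geometry_spec()].
#' @param mineralization a [mineralization_spec()] or `NULL` for an
#'   unmineralized fibril.
#' @param crosslink a [crosslink_spec()] or `NULL`.
#' @param seed integer; fixes any stochastic stream (the builder itself is
#'   deterministic, the seed is recorded for provenance).
#' @return a validated `fibril_model`.
#' @export
build_fibril <- function(geometry = geometry_spec(), mineralization = NULL,
                         crosslink = NULL, seed = 1L) {
  g <- geometry
  R <- g$diameter_nm * 10 / 2
  P <- g$periods
  D <- g$d_period
  Lx <- P * D
  f_over <- 1 - g$gap_fraction

  lat <- lattice_sites(R, g$n_molecules)
  sites <- lat$sites
  n_mol <- nrow(sites)
  phase <- ((sites$i + 2 * sites$j) %% P + P) %% P

  # deterministic molecule order: phase, then radius, then azimuth
  ord <- order(phase, sites$rho, atan2(sites$v, sites$u))
  sites <- sites[ord, ]
  phase <- phase[ord]

  # per-molecule bead counts
  if (!is.null(g$total_beads)) {
    base <- g$total_beads %/% n_mol
    extra <- g$total_beads - base * n_mol
    n_beads <- rep(base, n_mol)
    if (extra > 0) n_beads[seq_len(extra)] <- base + 1
  } else {
    m_p <- if (P >= 3) P - 2 else P - 1
    span <- (m_p + f_over) * D
    n_beads <- rep(round(span / (g$crimp_ratio * g$bead_spacing)) + 1, n_mol)
  }
  contour_base <- (min(n_beads) - 1) * g$bead_spacing

  # molecule axial span target: an integer number of D-periods plus the
  # overlap fraction, as close to crimp_ratio * contour as feasible
  m_p <- round(contour_base * g$crimp_ratio / D - f_over)
  ratio <- (m_p + f_over) * D / contour_base
  if (m_p < 0 || ratio > 0.999 || ratio < crimp_ratio(3))
    stop("geometry: no feasible molecule span for contour ", contour_base,
         " A and D-period ", D, " A")
  span_target <- (m_p + f_over) * D
  if (span_target >= Lx)
    stop("geometry: molecule span ", round(span_target), " A must be ",
         "smaller than the box length ", Lx, " A")

  # ratios within 0.15% of straight are built straight: the residual crimp
  # amplitude would be sub-Angstrom and its wavelength under-resolved
  u <- if (ratio > 0.9985) 0 else solve_crimp_u(ratio)
  field <- crimp_field(u, g$bead_spacing, Lx, g$crimp_wavelength)
  arc <- crimp_arc(field, c(-1, Lx + contour_base + 2 * g$bead_spacing))

  beads <- vector("list", n_mol)
  for (m in seq_len(n_mol)) {
    x0 <- phase[m] * D
    xb <- crimp_bead_x(arc, field, x0, n_beads[m], g$bead_spacing)
    yb <- sites$u[m] * lat$a + field$A * sin(field$k * xb)
    beads[[m]] <- tibble::tibble(
      species = "collagen", molecule = m,
      axial_index = seq_len(n_beads[m]),
      x = xb %% Lx, y = yb, z = rep(sites$v[m] * lat$a, n_beads[m]),
      vx = 0, vy = 0, vz = 0, mass = g$mass_collagen)
  }
  beads <- dplyr::bind_rows(beads)
  beads$id <- seq_len(nrow(beads))
  beads <- beads[, c("id", setdiff(names(beads), "id"))]

  # backbone bonds
  bp <- backbone_bond_params()
  first_id <- cumsum(c(1, n_beads[-n_mol]))
  bonds <- dplyr::bind_rows(lapply(seq_len(n_mol), function(m) {
    ids <- first_id[m] + seq_len(n_beads[m]) - 1
    tibble::tibble(i = ids[-length(ids)], j = ids[-1])
  }))
  bonds <- tibble::tibble(
    i = bonds$i, j = bonds$j, kind = "backbone",
    r0 = bp$r0, r1 = bp$r1, r_break = bp$r_break,
    kT0 = bp$kT0, kT1 = bp$kT1, broken = FALSE)

  max_cut <- max(default_pair_table()$cutoff)
  Lyz <- 2 * (R + field$A + max_cut + 10)
  box <- list(length = c(Lx, Lyz, Lyz), periodic = c(TRUE, FALSE, FALSE),
              L_ref = Lx)

  q <- seq_len(P) - 1
  gaps <- tibble::tibble(period = q,
                         gap_lo = q * D + f_over * D,
                         gap_hi = (q + 1) * D)

  registry <- list(
    n_molecules = n_mol, d_period = D, periods = P,
    diameter_nm = g$diameter_nm, lattice_a = lat$a,
    gap_fraction = g$gap_fraction, span_periods = m_p,
    crimp = field, gaps = gaps,
    molecules = tibble::tibble(
      molecule = seq_len(n_mol), phase = phase,
      y_site = sites$u * lat$a, z_site = sites$v * lat$a,
      n_beads = n_beads, start_x = phase * D),
    mineral_wt_pct = 0, equilibrated = FALSE, seed = as.integer(seed),
    volume_factor = pi * R^2,   # volume = volume_factor * Lx
    geometry = unclass(g))

  model <- fibril_model(beads, bonds,
                        angles = tibble::tibble(i = integer(), j = integer(),
                                                k = integer(), phi0 = numeric(),
                                                kB = numeric()),
                        box = box, registry = registry)
  model <- assign_angles(model)
  model$registry$molecules$contour0 <- molecule_contours(model)

  if (!is.null(mineralization) && mineralization$target_wt_pct > 0)
    model <- mineralize(model, mineralization)
  if (!is.null(crosslink) && crosslink$per_molecule > 0)
    model <- add_crosslinks(model, crosslink, seed = seed)

  viol <- validate_model(model)
  if (nrow(viol) > 0)
    stop("build_fibril produced an invalid model: ",
         paste(viol$check, collapse = ", "))
  model
}

molecule_contours <- function(model) {
  len <- bond_lengths(model)
  mol <- model$beads$molecule[model$bonds$i]
  as.numeric(tapply(len, mol, sum))
}

#' Assign equilibrium angles from the built geometry
#'
#' Every interior collagen bead triple receives one harmonic angle whose
#' equilibrium value is the measured initial angle rounded to the nearest
#' integer degree and clamped to \[164, 180\].
#'
#' @param model a `fibril_model` with molecules laid out.
#' @return the model with its `angles` table filled.
#' @export
assign_angles <- function(model) {
  d <- mcf_defaults()
  b <- model$beads
  coll <- b[b$species == "collagen", ]
  trip <- dplyr::bind_rows(lapply(split(coll$id, coll$molecule), function(ids) {
    n <- length(ids)
    if (n < 3) return(NULL)
    tibble::tibble(i = ids[1:(n - 2)], j = ids[2:(n - 1)], k = ids[3:n])
  }))
  if (is.null(trip) || nrow(trip) == 0) {
    model$angles <- tibble::tibble(i = integer(), j = integer(), k = integer(),
                                   phi0 = numeric(), kB = numeric())
    return(model)
  }
  tmp <- model
  tmp$angles <- tibble::tibble(i = trip$i, j = trip$j, k = trip$k,
                               phi0 = 180, kB = d$kB_angle)
  phi <- round(measure_angles(tmp))
  phi <- pmin(d$angle_max, pmax(d$angle_min, phi))
  model$angles <- tibble::tibble(i = trip$i, j = trip$j, k = trip$k,
                                 phi0 = phi, kB = d$kB_angle)
  model
}

# ---- mineralization -------------------------------------------------------

# FCC candidate sites with nearest-neighbour distance d filling one gap slab.
fcc_sites <- function(x_lo, x_hi, R, d) {
  a <- d * sqrt(2)
  nx <- ceiling((x_hi - x_lo) / a) + 1
  nr <- ceiling(2 * R / a) + 1
  base <- expand.grid(ix = 0:nx, iy = -nr:nr, iz = -nr:nr)
  offs <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  pts <- do.call(rbind, lapply(seq_len(4), function(o)
    cbind(x = (base$ix + offs[o, 1]) * a + x_lo,
          y = (base$iy + offs[o, 2]) * a,
          z = (base$iz + offs[o, 3]) * a)))
  pts <- pts[pts[, "x"] >= x_lo & pts[, "x"] <= x_hi &
               pts[, "y"]^2 + pts[, "z"]^2 <= R^2, , drop = FALSE]
  pts
}

#' Deposit intrafibrillar mineral to a target weight fraction
#'
#' Mineral beads are placed on a close-packed lattice that grows from the
#' two molecular terminal planes bounding each gap region (so low densities
#' produce two distinct clusters per gap), is clipped to the fibril
#' cylinder, and avoids overlap with collagen beads. Bead count is chosen
#' from the weight-fraction identity
#' \eqn{w = N_{min} m_{min} / (N_{min} m_{min} + N_{coll} m_{coll})}.
#'
#' @param model an unmineralized `fibril_model`.
#' @param spec a [mineralization_spec()].
#' @return the model with mineral beads appended.
#' @export
mineralize <- function(model, spec) {
  if (any(model$beads$species == "mineral"))
    stop("mineralize: model already contains mineral")
  w <- spec$target_wt_pct
  if (w == 0) return(model)
  reg <- model$registry
  if (is.null(reg$gaps)) stop("mineralize: model registry lacks gap bounds")
  m_min <- reg$geometry$mass_mineral %||% mcf_defaults()$mass_mineral
  M_coll <- sum(model$beads$mass)
  n_min <- round(w * M_coll / ((100 - w) * m_min))
  if (n_min == 0) stop("mineralize: target density too small for one bead")

  R <- reg$diameter_nm * 10 / 2 - spec$radial_margin
  field <- reg$crimp
  coll <- model$beads
  cand <- lapply(seq_len(nrow(reg$gaps)), function(gi) {
    lo <- reg$gaps$gap_lo[gi]; hi <- reg$gaps$gap_hi[gi]
    pts <- fcc_sites(lo + spec$lattice_spacing / 2,
                     hi - spec$lattice_spacing / 2, R, spec$lattice_spacing)
    if (nrow(pts) == 0) return(NULL)
    # rigid per-cluster shift onto the crimp field: sites follow the field
    # value at their terminal plane so each crystal keeps its exact lattice
    near_lo <- (pts[, "x"] - lo) <= (hi - pts[, "x"])
    shift <- field$A * sin(field$k * ifelse(near_lo, lo, hi))
    tibble::tibble(x = pts[, "x"], y = pts[, "y"] + shift, z = pts[, "z"],
                   d_term = pmin(pts[, "x"] - lo, hi - pts[, "x"]))
  })
  cand <- dplyr::bind_rows(cand)
  if (nrow(cand) == 0) stop("mineralize: gap regions admit no mineral sites")

  # drop sites overlapping collagen
  keep <- cpp_min_dist_keep(as.matrix(cand[, c("x", "y", "z")]),
                            cbind(coll$x, coll$y, coll$z),
                            spec$exclusion_radius, model$box$length[1])
  cand <- cand[keep, ]
  if (nrow(cand) < n_min) {
    max_w <- 100 * nrow(cand) * m_min / (nrow(cand) * m_min + M_coll)
    stop("mineralize: target ", w, " wt% unreachable; achievable maximum is ",
         round(max_w, 2), " wt% (", nrow(cand), " sites)")
  }
  ordc <- order(cand$d_term, cand$x, cand$y, cand$z)
  take <- cand[ordc[seq_len(n_min)], ]

  ids <- max(model$beads$id) + seq_len(n_min)
  mineral <- tibble::tibble(
    id = ids, species = "mineral", molecule = NA_integer_,
    axial_index = NA_integer_,
    x = take$x %% model$box$length[1], y = take$y, z = take$z,
    vx = 0, vy = 0, vz = 0, mass = m_min)
  model$beads <- dplyr::bind_rows(model$beads, mineral)

  got <- mineral_wt_pct(model)
  if (abs(got - w) > spec$tolerance_pct)
    stop("mineralize: achieved ", round(got, 3), " wt% outside +/-",
         spec$tolerance_pct, "% of target ", w)
  model$registry$mineral_wt_pct <- got
  model
}

# ---- crosslinks -----------------------------------------------------------

#' Add crosslink bonds at molecule termini
#'
#' For each molecule, up to `spec$per_molecule` crosslink bonds connect its
#' end beads to the nearest collagen bead of another molecule within the
#' search radius. Deterministic given the model and seed; an end with no
#' partner in range is skipped with a warning.
#'
#' @param model a `fibril_model` with the collagen lattice built.
#' @param spec a [crosslink_spec()].
#' @param seed integer, recorded for provenance.
#' @return the model with crosslink bonds appended.
#' @export
add_crosslinks <- function(model, spec, seed = 1L) {
  b <- model$beads
  coll <- b[b$species == "collagen", ]
  mols <- split(coll, coll$molecule)
  bp <- backbone_bond_params()
  Lx <- model$box$length[1]
  new <- list(); skipped <- 0L
  used <- integer(0)
  for (m in names(mols)) {
    mb <- mols[[m]]
    ends <- c(mb$id[which.min(mb$axial_index)], mb$id[which.max(mb$axial_index)])
    n_placed <- 0L
    for (e in ends) {
      if (n_placed >= spec$per_molecule) break
      eb <- b[b$id == e, ]
      other <- coll[coll$molecule != eb$molecule, ]
      dx <- min_image_dx(other$x - eb$x, Lx)
      d2 <- dx^2 + (other$y - eb$y)^2 + (other$z - eb$z)^2
      ok <- which(d2 <= spec$search_radius^2)
      if (length(ok) == 0) { skipped <- skipped + 1L; next }
      partner <- other$id[ok[which.min(d2[ok])]]
      key <- paste(sort(c(e, partner)), collapse = "-")
      if (key %in% used) next  # this pair is already crosslinked
      used <- c(used, key)
      new[[length(new) + 1]] <- tibble::tibble(
        i = e, j = partner, kind = "crosslink",
        r0 = bp$r0, r1 = bp$r1, r_break = bp$r_break * spec$r_break_scale,
        kT0 = bp$kT0, kT1 = bp$kT1, broken = FALSE)
      n_placed <- n_placed + 1L
    }
  }
  if (skipped > 0)
    warning("add_crosslinks: ", skipped,
            " crosslink(s) skipped (no eligible partner in range)")
  if (length(new) > 0)
    model$bonds <- dplyr::bind_rows(model$bonds, dplyr::bind_rows(new))
  model$registry$crosslinks <- length(new)
  model
}

# ---- fixtures -------------------------------------------------------------

#' Build small deterministic test systems
#'
#' @param kind `"single_molecule"` (one straight chain), `"molecule_pair"`
#'   (two parallel chains at lattice spacing) or `"mini_fibril"` (reduced
#'   diameter/period fibril, optionally mineralized).
#' @param n_beads beads per chain for the chain fixtures.
#' @param periodic_chain logical; close the chain through the periodic
#'   axial boundary (box length = `n_beads * spacing`, one seam bond). A
#'   periodic chain percolates the box, so box-deformation tension loads
#'   its bonds directly - the configuration used for single-molecule
#'   tensile tests.
#' @param separation chain separation in A for `molecule_pair`.
#' @param diameter_nm,d_period,periods,crimp_ratio mini-fibril geometry
#'   overrides; the default mini fibril is built with near-straight
#'   molecules (`crimp_ratio = 0.999`) so its compaction resistance is not
#'   dominated by a coherent crimp mode.
#' @param mineral_wt_pct mini-fibril mineral target (0 = none).
#' @param crosslink optional [crosslink_spec()] for the mini fibril.
#' @param seed integer seed.
#' @return a `fibril_model`.
#' @export
build_fixture <- function(kind = c("single_molecule", "molecule_pair",
                                   "mini_fibril"),
                          n_beads = 215, periodic_chain = FALSE,
                          separation = 14.72,
                          diameter_nm = 6, d_period = 335, periods = 2,
                          crimp_ratio = 0.999, mineral_wt_pct = 0,
                          crosslink = NULL, seed = 1L) {
  kind <- match.arg(kind)
  d <- mcf_defaults()
  if (kind %in% c("single_molecule", "molecule_pair")) {
    n_chain <- if (kind == "molecule_pair") 2L else 1L
    span <- (n_beads - 1) * d$r0
    # open chain: vacuum gap just beyond the largest cutoff so the chain
    # does not touch its own periodic image; periodic chain: the box length
    # is exactly the closed-chain contour
    Lx <- if (periodic_chain) n_beads * d$r0
          else span + 1.2 * max(default_pair_table()$cutoff)
    beads <- dplyr::bind_rows(lapply(seq_len(n_chain), function(m)
      tibble::tibble(
        species = "collagen", molecule = m, axial_index = seq_len(n_beads),
        x = (if (periodic_chain) 0 else 25) + d$r0 * (seq_len(n_beads) - 1),
        y = (m - 1) * separation, z = 0,
        vx = 0, vy = 0, vz = 0, mass = d$mass_collagen)))
    beads$id <- seq_len(nrow(beads))
    beads <- beads[, c("id", setdiff(names(beads), "id"))]
    bp <- backbone_bond_params()
    bonds <- dplyr::bind_rows(lapply(seq_len(n_chain), function(m) {
      ids <- (m - 1) * n_beads + seq_len(n_beads)
      tb <- tibble::tibble(i = ids[-n_beads], j = ids[-1])
      if (periodic_chain)
        tb <- dplyr::bind_rows(tb, tibble::tibble(i = ids[n_beads],
                                                  j = ids[1]))
      tb
    }))
    bonds <- tibble::tibble(i = bonds$i, j = bonds$j, kind = "backbone",
                            r0 = bp$r0, r1 = bp$r1, r_break = bp$r_break,
                            kT0 = bp$kT0, kT1 = bp$kT1, broken = FALSE)
    Lyz <- 2 * (separation + max(default_pair_table()$cutoff) + 30)
    model <- fibril_model(
      beads, bonds,
      angles = tibble::tibble(i = integer(), j = integer(), k = integer(),
                              phi0 = numeric(), kB = numeric()),
      box = list(length = c(Lx, Lyz, Lyz),
                 periodic = c(TRUE, FALSE, FALSE), L_ref = Lx),
      registry = list(n_molecules = n_chain, equilibrated = FALSE,
                      crimp = list(u = 0, k = 0, A = 0),
                      volume_factor = n_chain * molecule_cross_section(),
                      seed = as.integer(seed),
                      molecules = tibble::tibble(
                        molecule = seq_len(n_chain), phase = 0,
                        n_beads = n_beads)))
    model <- assign_angles(model)
    model$registry$molecules$contour0 <- molecule_contours(model)
    return(model)
  }
  g <- geometry_spec(diameter_nm = diameter_nm, d_period = d_period,
                     periods = periods, n_molecules = NULL, total_beads = NULL,
                     crimp_ratio = crimp_ratio, crimp_wavelength = NULL)
  ms <- if (mineral_wt_pct > 0)
    mineralization_spec(target_wt_pct = mineral_wt_pct) else NULL
  build_fibril(g, ms, crosslink, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
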