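# File formats: LAMMPS data dialect (bonds + angles) for particle systems,
# LAMMPS-style dump / XYZ trajectories, YAML run configuration.
# Coordinates are written in A; box bounds are half-open [lo, hi); the
# fibril axis is x. Broken-bond state and the build registry are persisted
# in `#mf`-prefixed comment lines so LAMMPS itself can still read the file.

#' Write a particle system in the LAMMPS data dialect
#'
#' Atom style `molecular` (id mol type x y z) with Masses, PairIJ Coeffs,
#' Bond Coeffs (bilinear: kT0 kT1 r0 r1 r_break), Angle Coeffs (kB phi0),
#' Velocities, Bonds and Angles sections. Broken-bond flags and the build
#' registry ride along as `#mf` comment lines; [read_particle_system()]
#' restores them, so `read(write(m))` reproduces the model field for field.
#'
#' @param model a `fibril_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_particle_system <- function(model, path) {
  b <- model$beads; bd <- model$bonds; an <- model$angles
  pt <- model$pair_table
  # bond types by kind + parameter set
  bkey <- paste(bd$kind, bd$r0, bd$r1, bd$r_break, bd$kT0, bd$kT1)
  btypes <- unique(bkey)
  btype_id <- match(bkey, btypes)
  akey <- paste(an$phi0, an$kB)
  atypes <- unique(akey)
  atype_id <- match(akey, atypes)
  L <- model$box$length
  lines <- c(
    "LAMMPS data file via minfibril (mesoscale mineralized collagen fibril)",
    "",
    sprintf("%d atoms", nrow(b)),
    sprintf("%d bonds", nrow(bd)),
    sprintf("%d angles", nrow(an)),
    "2 atom types",
    sprintf("%d bond types", max(1, length(btypes))),
    sprintf("%d angle types", max(1, length(atypes))),
    "",
    sprintf("0.0 %.10g xlo xhi", L[1]),
    sprintf("%.10g %.10g ylo yhi", -L[2] / 2, L[2] / 2),
    sprintf("%.10g %.10g zlo zhi", -L[3] / 2, L[3] / 2),
    "",
    "Masses",
    "",
    sprintf("1 %.10g", unique(b$mass[b$species == "collagen"])[1] %||% 1324),
    sprintf("2 %.10g", if (any(b$species == "mineral"))
      unique(b$mass[b$species == "mineral"])[1] else mcf_defaults()$mass_mineral),
    "",
    "PairIJ Coeffs",
    "",
    sprintf("1 1 %.10g %.10g %.10g", pt$epsilon[pt$class == "collagen"],
            pt$sigma[pt$class == "collagen"], pt$cutoff[pt$class == "collagen"]),
    sprintf("1 2 %.10g %.10g %.10g", pt$epsilon[pt$class == "inter"],
            pt$sigma[pt$class == "inter"], pt$cutoff[pt$class == "inter"]),
    sprintf("2 2 %.10g %.10g %.10g", pt$epsilon[pt$class == "mineral"],
            pt$sigma[pt$class == "mineral"], pt$cutoff[pt$class == "mineral"]))
  if (length(btypes) > 0 && nrow(bd) > 0) {
    bp <- bd[match(btypes, bkey), ]
    lines <- c(lines, "", "Bond Coeffs", "",
               sprintf("%d %.10g %.10g %.10g %.10g %.10g", seq_along(btypes),
                       bp$kT0, bp$kT1, bp$r0, bp$r1, bp$r_break))
  }
  if (length(atypes) > 0 && nrow(an) > 0) {
    ap <- an[match(atypes, akey), ]
    lines <- c(lines, "", "Angle Coeffs", "",
               sprintf("%d %.10g %.10g", seq_along(atypes), ap$kB, ap$phi0))
  }
  mol <- ifelse(is.na(b$molecule), 0L, b$molecule)
  typ <- ifelse(b$species == "mineral", 2L, 1L)
  lines <- c(lines, "", "Atoms # molecular", "",
             sprintf("%d %d %d %.10g %.10g %.10g", b$id, mol, typ,
                     b$x, b$y, b$z),
             "", "Velocities", "",
             sprintf("%d %.10g %.10g %.10g", b$id, b$vx, b$vy, b$vz))
  if (nrow(bd) > 0)
    lines <- c(lines, "", "Bonds", "",
               sprintf("%d %d %d %d", seq_len(nrow(bd)), btype_id, bd$i, bd$j))
  if (nrow(an) > 0)
    lines <- c(lines, "", "Angles", "",
               sprintf("%d %d %d %d %d", seq_len(nrow(an)), atype_id,
                       an$i, an$j, an$k))
  # custom state: broken flags, bead metadata, registry (comment lines so the
  # file stays LAMMPS-parseable)
  lines <- c(lines, "",
    paste0("#mf broken ", jsonlite::toJSON(which(bd$broken))),
    paste0("#mf axial_index ",
           jsonlite::toJSON(ifelse(is.na(b$axial_index), -1L, b$axial_index))),
    paste0("#mf bond_kind ", jsonlite::toJSON(bd$kind)),
    paste0("#mf registry ",
           jsonlite::toJSON(serialize_registry(model$registry),
                            digits = NA, null = "null")))
  writeLines(lines, path)
  invisible(path)
}

serialize_registry <- function(reg) {
  reg$molecules <- if (!is.null(reg$molecules)) as.data.frame(reg$molecules)
  reg$gaps <- if (!is.null(reg$gaps)) as.data.frame(reg$gaps)
  reg
}

deserialize_registry <- function(reg) {
  if (!is.null(reg$molecules)) reg$molecules <- tibble::as_tibble(reg$molecules)
  if (!is.null(reg$gaps)) reg$gaps <- tibble::as_tibble(reg$gaps)
  for (nm in c("n_molecules", "periods", "span_periods", "seed", "crosslinks"))
    if (!is.null(reg[[nm]])) reg[[nm]] <- as.integer(reg[[nm]])
  reg
}

#' Read a particle system written by [write_particle_system()]
#'
#' @param path file path.
#' @return a `fibril_model`.
#' @export
read_particle_system <- function(path) {
  raw <- readLines(path)
  mf <- raw[startsWith(raw, "#mf ")]
  txt <- raw[!startsWith(raw, "#")]
  strip <- function(s) sub("\\s*#.*$", "", s)
  parse_err <- function(line_no, what)
    stop("parse error at line ", line_no, ": ", what, call. = FALSE)

  header_count <- function(word) {
    hit <- grep(paste0("^\\s*\\d+\\s+", word, "\\s*$"), txt)
    if (length(hit) == 0) parse_err(1, paste("missing", word, "count"))
    as.integer(sub("^\\s*(\\d+).*$", "\\1", txt[hit[1]]))
  }
  n_atoms <- header_count("atoms")
  n_bonds <- header_count("bonds")
  n_angles <- header_count("angles")

  get_bounds <- function(tag) {
    hit <- grep(paste0(tag, "\\b"), txt)
    if (length(hit) == 0) parse_err(1, paste("missing", tag))
    as.numeric(strsplit(trimws(strip(txt[hit[1]])), "\\s+")[[1]][1:2])
  }
  xb <- get_bounds("xlo xhi"); yb <- get_bounds("ylo yhi")
  zb <- get_bounds("zlo zhi")

  section <- function(name, n, required = TRUE) {
    hit <- grep(paste0("^\\s*", name, "\\b"), txt)
    if (length(hit) == 0) {
      if (required) parse_err(1, paste("missing", name, "section"))
      return(NULL)
    }
    start <- hit[1] + 1
    rows <- character(0); ln <- start
    while (ln <= length(txt) && length(rows) < n) {
      s <- trimws(strip(txt[ln]))
      if (nzchar(s)) {
        if (grepl("^[A-Za-z]", s)) break
        rows <- c(rows, s)
      }
      ln <- ln + 1
    }
    if (length(rows) < n)
      parse_err(ln, paste("section", name, "has", length(rows),
                          "rows, expected", n))
    do.call(rbind, lapply(rows, function(s)
      as.numeric(strsplit(s, "\\s+")[[1]])))
  }

  masses <- section("Masses", 2)
  pair <- section("PairIJ Coeffs", 3)
  atoms <- section("Atoms", n_atoms)
  vel <- section("Velocities", n_atoms, required = FALSE)
  nbt <- header_count("bond types"); nat <- header_count("angle types")
  bond_coeffs <- if (n_bonds > 0) section("Bond Coeffs", nbt) else NULL
  angle_coeffs <- if (n_angles > 0) section("Angle Coeffs", nat) else NULL
  bonds <- if (n_bonds > 0) section("Bonds", n_bonds) else NULL
  angles <- if (n_angles > 0) section("Angles", n_angles) else NULL

  mf_get <- function(key) {
    hit <- mf[startsWith(mf, paste0("#mf ", key, " "))]
    if (length(hit) == 0) return(NULL)
    jsonlite::fromJSON(sub(paste0("^#mf ", key, " "), "", hit[1]))
  }
  ord <- order(atoms[, 1])
  atoms <- atoms[ord, , drop = FALSE]
  axial <- mf_get("axial_index")
  beads <- tibble::tibble(
    id = as.integer(atoms[, 1]),
    species = ifelse(atoms[, 3] == 2, "mineral", "collagen"),
    molecule = ifelse(atoms[, 2] == 0, NA_integer_, as.integer(atoms[, 2])),
    axial_index = if (!is.null(axial))
      ifelse(axial == -1, NA_integer_, as.integer(axial)) else NA_integer_,
    x = atoms[, 4], y = atoms[, 5], z = atoms[, 6],
    vx = 0, vy = 0, vz = 0,
    mass = ifelse(atoms[, 3] == 2, masses[2, 2], masses[1, 2]))
  if (!is.null(vel)) {
    vord <- match(beads$id, vel[, 1])
    beads$vx <- vel[vord, 2]; beads$vy <- vel[vord, 3]; beads$vz <- vel[vord, 4]
  }
  kind <- mf_get("bond_kind")
  bonds_tb <- if (n_bonds > 0) {
    bt <- bond_coeffs[bonds[, 2], , drop = FALSE]
    tibble::tibble(i = as.integer(bonds[, 3]), j = as.integer(bonds[, 4]),
                   kind = if (!is.null(kind)) kind else "backbone",
                   r0 = bt[, 4], r1 = bt[, 5], r_break = bt[, 6],
                   kT0 = bt[, 2], kT1 = bt[, 3], broken = FALSE)
  } else tibble::tibble(i = integer(), j = integer(), kind = character(),
                        r0 = numeric(), r1 = numeric(), r_break = numeric(),
                        kT0 = numeric(), kT1 = numeric(), broken = logical())
  broken_idx <- mf_get("broken")
  if (!is.null(broken_idx) && length(broken_idx) > 0)
    bonds_tb$broken[as.integer(broken_idx)] <- TRUE
  angles_tb <- if (n_angles > 0) {
    at <- angle_coeffs[angles[, 2], , drop = FALSE]
    tibble::tibble(i = as.integer(angles[, 3]), j = as.integer(angles[, 4]),
                   k = as.integer(angles[, 5]), phi0 = at[, 3], kB = at[, 2])
  } else tibble::tibble(i = integer(), j = integer(), k = integer(),
                        phi0 = numeric(), kB = numeric())
  pair_tb <- tibble::tibble(
    class = c("collagen", "inter", "mineral"),
    sigma = pair[, 4], epsilon = pair[, 3], cutoff = pair[, 5])
  pair_tb <- pair_tb[match(c("collagen", "mineral", "inter"), pair_tb$class), ]
  reg <- mf_get("registry")
  reg <- if (!is.null(reg)) deserialize_registry(reg) else list()
  fibril_model(beads, bonds_tb, angles_tb, pair_tb,
               box = list(length = c(xb[2] - xb[1], yb[2] - yb[1],
                                     zb[2] - zb[1]),
                          periodic = c(TRUE, FALSE, FALSE),
                          L_ref = xb[2] - xb[1]),
               registry = reg)
}

#' Write a trajectory in LAMMPS dump or XYZ format
#'
#' @param frames list of frames (as returned in a run's `frames`).
#' @param path output path.
#' @param model the `fibril_model` (for species and box geometry).
#' @param format `"dump"` or `"xyz"`.
#' @param per_bead_strain optional list of per-bead strain vectors (one per
#'   frame) appended as an extra dump column.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, path, model, format = c("dump", "xyz"),
                             per_bead_strain = NULL) {
  format <- match.arg(format)
  typ <- ifelse(model$beads$species == "mineral", 2L, 1L)
  n <- nrow(model$beads)
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(frames)) {
    f <- frames[[fi]]
    if (format == "dump") {
      cols <- sprintf("%d %d %.6f %.6f %.6f", seq_len(n), typ,
                      f$pos[, 1], f$pos[, 2], f$pos[, 3])
      hdr <- "ITEM: ATOMS id type x y z"
      if (!is.null(per_bead_strain)) {
        cols <- paste(cols, sprintf("%.6f", per_bead_strain[[fi]]))
        hdr <- paste(hdr, "strain")
      }
      writeLines(c("ITEM: TIMESTEP", as.character(f$step),
                   "ITEM: NUMBER OF ATOMS", as.character(n),
                   "ITEM: BOX BOUNDS pp ff ff",
                   sprintf("0.0 %.6f", f$Lx),
                   sprintf("%.6f %.6f", -model$box$length[2] / 2,
                           model$box$length[2] / 2),
                   sprintf("%.6f %.6f", -model$box$length[3] / 2,
                           model$box$length[3] / 2),
                   hdr, cols), con)
    } else {
      writeLines(c(as.character(n),
                   sprintf("step %d Lx %.6f", f$step, f$Lx),
                   sprintf("%s %.6f %.6f %.6f",
                           ifelse(typ == 2, "Mn", "C"),
                           f$pos[, 1], f$pos[, 2], f$pos[, 3])), con)
    }
  }
  invisible(path)
}

#' Write / read a run configuration (YAML)
#'
#' A run configuration bundles the geometry, mineralization, crosslink and
#' engine sections plus a global seed and output directory; together with
#' the package version it reproduces a run's outputs.
#'
#' @param config nested list (sections `geometry`, `mineralization`,
#'   `crosslink`, `engine`, `seed`, `outdir`).
#' @param path YAML file path.
#' @return `write_run_config`: the path; `read_run_config`: the list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

config_to_specs <- function(cfg) {
  g <- do.call(geometry_spec, cfg$geometry %||% list())
  m <- if (!is.null(cfg$mineralization))
    do.call(mineralization_spec, cfg$mineralization) else NULL
  x <- if (!is.null(cfg$crosslink)) do.call(crosslink_spec, cfg$crosslink)
       else NULL
  e <- do.call(engine_config, cfg$engine %||% list())
  list(geometry = g, mineralization = m, crosslink = x, engine = e,
       seed = cfg$seed %||% 1L)
}
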