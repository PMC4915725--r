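# Mechanical analysis: stress-strain curves, deformation-regime
# segmentation by piecewise-linear change-point fitting, moduli, toughness,
# contraction / internal stress, and density-normalized performance.

#' Stress-strain curve container
#'
#' A tibble of (strain, stress) with the two reference lengths needed to
#' convert between the relaxed-length strain convention (strain measured
#' from the relaxed, possibly mineral-contracted length) and the fixed-L0
#' convention (strain measured from the unmineralized reference length):
#' \eqn{\epsilon_{L_0} = (L_{relaxed}/L_0)(1 + \epsilon_{relaxed}) - 1}.
#'
#' @param strain strictly increasing strain values (fraction).
#' @param stress stress values in GPa.
#' @param L_relaxed relaxed axial length the strain is measured from, A.
#' @param L0 unmineralized reference length, A.
#' @param convention which convention `strain` is in.
#' @return a `stress_strain_curve` tibble with columns `strain`, `stress`.
#' @export
stress_strain_curve <- function(strain, stress, L_relaxed = NA_real_,
                                L0 = NA_real_,
                                convention = c("relaxed-length", "fixed-L0")) {
  convention <- match.arg(convention)
  stopifnot(length(strain) == length(stress))
  if (length(strain) > 1 && any(diff(strain) <= 0))
    stop("stress_strain_curve: strain grid must be strictly increasing")
  out <- tibble::tibble(strain = as.numeric(strain),
                        stress = as.numeric(stress))
  class(out) <- c("stress_strain_curve", class(out))
  attr(out, "L_relaxed") <- L_relaxed
  attr(out, "L0") <- L0
  attr(out, "convention") <- convention
  out
}

#' Convert a curve between strain conventions
#' @param curve a `stress_strain_curve`.
#' @param to target convention.
#' @return the converted curve.
#' @export
convert_strain <- function(curve, to = c("fixed-L0", "relaxed-length")) {
  to <- match.arg(to)
  from <- attr(curve, "convention")
  if (from == to) return(curve)
  Lr <- attr(curve, "L_relaxed"); L0 <- attr(curve, "L0")
  if (is.na(Lr) || is.na(L0))
    stop("convert_strain: reference lengths not stored on the curve")
  s <- if (to == "fixed-L0") (Lr / L0) * (1 + curve$strain) - 1
       else (L0 / Lr) * (1 + curve$strain) - 1
  stress_strain_curve(s, curve$stress, L_relaxed = Lr, L0 = L0,
                      convention = to)
}

# index of the ultimate point: global stress maximum, last point on ties
ultimate_index <- function(curve) {
  m <- max(curve$stress)
  max(which(curve$stress >= m - 1e-12))
}

#' Toughness: area under the curve up to the ultimate strength
#'
#' Trapezoidal integral of stress over strain from the first sample to the
#' strain of maximum stress (ties resolved to the last attaining point).
#'
#' @param curve a `stress_strain_curve`.
#' @param require_interior_max error if the stress is still strictly rising
#'   at the final sample (curve truncated before its maximum).
#' @return toughness in GPa (stress x strain).
#' @export
toughness <- function(curve, require_interior_max = FALSE) {
  iu <- ultimate_index(curve)
  if (require_interior_max && iu == nrow(curve) &&
      nrow(curve) > 1 &&
      curve$stress[iu] > curve$stress[iu - 1] + 1e-12)
    stop("toughness: curve truncated before reaching its maximum")
  s <- curve$strain[1:iu]; y <- curve$stress[1:iu]
  if (iu < 2) return(0)
  sum(diff(s) * (y[-1] + y[-iu]) / 2)
}

#' Least-squares modulus over a strain window
#'
#' @param curve a `stress_strain_curve`.
#' @param window length-2 strain range.
#' @return tibble: `modulus_gpa`, `ci_lo`, `ci_hi` (95%), `r_squared`, `n`.
#' @export
fit_modulus <- function(curve, window) {
  sel <- curve$strain >= window[1] & curve$strain <= window[2]
  if (sum(sel) < 5)
    stop("fit_modulus: fewer than 5 samples in the window")
  d <- curve[sel, ]
  if (stats::sd(d$strain) == 0) stop("fit_modulus: singular fit")
  fit <- stats::lm(stress ~ strain, data = d)
  # exact lines make the residual variance zero; the CI is then degenerate
  ci <- suppressWarnings(stats::confint(fit)["strain", ])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  tibble::tibble(modulus_gpa = stats::coef(fit)[["strain"]],
                 ci_lo = ci[[1]], ci_hi = ci[[2]],
                 r_squared = r2, n = nrow(d))
}

# ---- change-point segmentation --------------------------------------------

# O(1) segment SSE from prefix sums of a linear fit
seg_cost_fun <- function(x, y) {
  n <- length(x)
  cx <- cumsum(c(0, x)); cy <- cumsum(c(0, y))
  cxx <- cumsum(c(0, x^2)); cxy <- cumsum(c(0, x * y)); cyy <- cumsum(c(0, y^2))
  function(i, j) {  # inclusive 1-based range
    m <- j - i + 1
    sx <- cx[j + 1] - cx[i]; sy <- cy[j + 1] - cy[i]
    sxx <- cxx[j + 1] - cxx[i]; sxy <- cxy[j + 1] - cxy[i]
    syy <- cyy[j + 1] - cyy[i]
    vxx <- sxx - sx * sx / m
    if (vxx <= 1e-14) return(syy - sy * sy / m)
    b <- (sxy - sx * sy / m) / vxx
    (syy - sy * sy / m) - b * (sxy - sx * sy / m)
  }
}

# dynamic-programming piecewise-linear fit; returns breakpoint indices
dp_segment <- function(x, y, k_max = 6, min_len = 5) {
  n <- length(x)
  cost <- seg_cost_fun(x, y)
  k_max <- min(k_max, floor(n / min_len))
  if (k_max < 1) return(list(breaks = integer(), k = 1))
  C <- matrix(Inf, k_max, n)   # C[k, j] best cost of first j points in k segs
  B <- matrix(0L, k_max, n)
  for (j in min_len:n) C[1, j] <- cost(1, j)
  if (k_max >= 2) {
    for (k in 2:k_max) {
      for (j in (k * min_len):n) {
        lo <- (k - 1) * min_len; hi <- j - min_len
        if (hi < lo) next
        prev <- C[k - 1, lo:hi] + vapply(lo:hi, function(t) cost(t + 1, j),
                                         numeric(1))
        t_best <- which.min(prev)
        C[k, j] <- prev[t_best]
        B[k, j] <- lo + t_best - 1L
      }
    }
  }
  # BIC model selection
  rss <- pmax(C[, n], 1e-12)
  pars <- 3 * seq_len(k_max) - 1
  bic <- n * log(rss / n) + pars * log(n)
  k <- which.min(bic)
  breaks <- integer(0)
  j <- n
  if (k >= 2) for (kk in k:2) { t <- B[kk, j]; breaks <- c(t, breaks); j <- t }
  list(breaks = breaks, k = k)
}

smooth_curve <- function(curve, window_strain = 0.01) {
  if (nrow(curve) < 7) return(curve)
  dx <- stats::median(diff(curve$strain))
  w <- max(1, round(window_strain / dx))
  if (w %% 2 == 0) w <- w + 1
  if (w <= 1) return(curve)
  sm <- stats::filter(curve$stress, rep(1 / w, w), sides = 2)
  y <- as.numeric(sm)
  h <- (w - 1) / 2
  y[seq_len(h)] <- curve$stress[seq_len(h)]
  y[(nrow(curve) - h + 1):nrow(curve)] <-
    curve$stress[(nrow(curve) - h + 1):nrow(curve)]
  curve$stress_smooth <- y
  curve
}

#' Count discrete stress-drop (slip) events on a curve
#'
#' Detects the saw-tooth signature of repeated intermolecular slippage and
#' mineral-collagen sliding: on the smoothed curve, each local maximum
#' followed by a decline of at least `min_drop_frac` of the global maximum
#' before the next rise counts as one event.
#'
#' @param curve a `stress_strain_curve`.
#' @param window strain range to scan; default from 10% strain to the
#'   ultimate point.
#' @param min_drop_frac minimum drop depth as a fraction of the global
#'   stress maximum.
#' @param smooth_window smoothing window in strain units.
#' @return integer number of slip events.
#' @export
stress_drop_events <- function(curve, window = NULL, min_drop_frac = 0.02,
                               smooth_window = 0.01) {
  iu <- ultimate_index(curve)
  if (is.null(window)) window <- c(0.10, curve$strain[iu])
  sc <- smooth_curve(curve, smooth_window)
  y <- sc[["stress_smooth"]] %||% sc$stress
  sel <- curve$strain >= window[1] & curve$strain <= window[2]
  y <- y[sel]
  if (length(y) < 5) return(0L)
  smax <- max(curve$stress)
  events <- 0L
  peak <- y[1]
  dropping <- FALSE
  for (v in y[-1]) {
    if (v > peak) {
      peak <- v
      dropping <- FALSE
    } else if (!dropping && peak - v >= min_drop_frac * smax) {
      events <- events + 1L
      dropping <- TRUE
    } else if (dropping && v > peak - 0.5 * min_drop_frac * smax) {
      # recovered: rearm on the next rise above the current peak
      peak <- v
      dropping <- FALSE
    }
  }
  events
}

#' Segment a stress-strain curve into deformation regimes
#'
#' Smooths the curve (centred moving average over a 1%-strain window),
#' decimates it, and fits a piecewise-linear model by exact
#' dynamic-programming change-point detection with BIC model selection.
#' Segments are then labelled: an initial low-slope toe (uncrimping), the
#' primary elastic regime I-a, an optional distinct intermediate regime I-b,
#' a sliding/slippage regime II (slope drop with stress oscillation,
#' saw-tooth), a stiffening regime III (slope rise, backbone stretching),
#' and post-peak failure IV.
#'
#' @param curve a `stress_strain_curve`.
#' @param k_max maximum number of segments.
#' @param max_points decimation target for the fit grid.
#' @param smooth_window smoothing window in strain units.
#' @return a `regime_report` list: `segments` tibble (`regime`,
#'   `strain_lo`, `strain_hi`, `modulus_gpa`, `oscillation`, `n`),
#'   `breakpoints` (strain values), `toe_extent`, `has_sawtooth`,
#'   `partial` flag when fewer than 2 regimes could be resolved.
#' @export
segment_regimes <- function(curve, k_max = 6, max_points = 400,
                            smooth_window = 0.01) {
  sc <- smooth_curve(curve, smooth_window)
  y_all <- sc[["stress_smooth"]] %||% sc$stress
  # restrict to the pre/peri-failure range: up to ultimate point plus a tail
  iu <- ultimate_index(curve)
  i_hi <- min(nrow(curve), iu + max(5, round(0.05 * nrow(curve))))
  x <- curve$strain[1:i_hi]; y <- y_all[1:i_hi]; y_raw <- curve$stress[1:i_hi]
  if (length(x) > max_points) {
    idx <- unique(round(seq(1, length(x), length.out = max_points)))
    x <- x[idx]; y <- y[idx]; y_raw <- y_raw[idx]
  }
  partial <- length(x) < 10
  # change points are fitted on the raw decimated curve: pre-smoothing
  # correlates the noise and biases the BIC toward spurious segments at
  # rounded corners; the smoothed curve informs only the event detection
  dp <- dp_segment(x, y_raw, k_max = k_max)
  bounds <- c(1, dp$breaks, length(x))
  segs <- lapply(seq_len(length(bounds) - 1), function(s) {
    i0 <- if (s == 1) bounds[1] else bounds[s] + 1
    i1 <- bounds[s + 1]
    xs <- x[i0:i1]; yr <- y_raw[i0:i1]
    fit <- stats::lm(yr ~ xs)
    res_raw <- stats::residuals(fit)
    tibble::tibble(strain_lo = xs[1], strain_hi = xs[length(xs)],
                   modulus_gpa = stats::coef(fit)[[2]],
                   oscillation = stats::sd(res_raw), n = length(xs))
  })
  segs <- dplyr::bind_rows(segs)
  segs$regime <- label_regimes(segs)
  toe <- segs$strain_hi[segs$regime == "toe"]
  has_saw <- "II" %in% segs$regime && stress_drop_events(curve) >= 3
  structure(list(
    segments = segs[, c("regime", "strain_lo", "strain_hi", "modulus_gpa",
                        "oscillation", "n")],
    breakpoints = x[dp$breaks],
    toe_extent = if (length(toe) > 0) toe[1] else 0,
    has_sawtooth = has_saw,
    partial = partial || nrow(segs) < 2
  ), class = "regime_report")
}

# sequential regime labelling from segment slopes
label_regimes <- function(segs) {
  k <- nrow(segs)
  lab <- rep(NA_character_, k)
  s <- segs$modulus_gpa
  i <- 1
  # toe: initial low-slope region ending by ~12% strain
  if (k >= 2 && s[1] < 0.5 * s[2] && segs$strain_hi[1] <= 0.12) {
    lab[1] <- "toe"; i <- 2
  }
  if (i <= k) { lab[i] <- "I-a"; i <- i + 1 }
  # I-b: distinct intermediate slope, still a substantial fraction of I-a
  if (i <= k && i + 1 <= k && s[i] > 0 &&
      s[i] < 0.9 * s[i - 1] && s[i] > 0.4 * s[i - 1] &&
      s[i + 1] < s[i]) {
    lab[i] <- "I-b"; i <- i + 1
  }
  prev_elastic <- max(which(!is.na(lab)))
  if (i <= k) {
    # II: slope drop relative to the elastic regime
    if (s[i] < 0.75 * s[prev_elastic]) { lab[i] <- "II"; i <- i + 1 }
  }
  if (i <= k) {
    last_lab <- max(which(!is.na(lab)))
    if (s[i] > s[last_lab]) { lab[i] <- "III"; i <- i + 1 }
  }
  while (i <= k) {
    lab[i] <- if (s[i] < 0) "IV" else
      if (!"II" %in% lab) "II" else if (!"III" %in% lab) "III" else "IV"
    i <- i + 1
  }
  lab
}

#' @export
print.regime_report <- function(x, ...) {
  cat("<regime_report>", nrow(x$segments), "segments; toe extent",
      signif(x$toe_extent, 3), "; saw-tooth:", x$has_sawtooth, "\n")
  print(x$segments)
  invisible(x)
}

# ---- contraction / internal stress ----------------------------------------

#' Mineral-induced contraction and internal stress
#'
#' Contraction is the relative shortening of the relaxed mineralized fibril
#' against the unmineralized reference length L0. Internal stress is the
#' axial virial stress measured with the box re-extended (affinely) to L0
#' and held there under the thermostat.
#'
#' @param state an equilibrated `engine_state`.
#' @param L0 unmineralized reference length in A.
#' @param hold_ns hold duration for the internal-stress average, ns.
#' @param sample_every sampling stride in steps.
#' @return tibble: `contraction_pct`, `internal_stress_gpa`.
#' @export
contraction_and_internal_stress <- function(state, L0, hold_ns = 0.1,
                                            sample_every = 100) {
  if (missing(L0) || is.null(L0) || !is.finite(L0))
    stop("contraction_and_internal_stress: reference length L0 is required")
  L_rel <- state$model$box$length[1]
  contraction <- 100 * (L0 - L_rel) / L0
  # re-extend to L0 and hold
  st <- state
  mu <- L0 / L_rel
  st$model$beads$x <- st$model$beads$x * mu
  st$model$box$length[1] <- L0
  n_steps <- max(100, round(hold_ns * 1e6 / st$config$timestep))
  res <- run_engine(st, n_steps, thermostat = TRUE, barostat = FALSE,
                    sample_every = sample_every)
  sam <- res$samples
  keep <- sam$step >= 0.5 * max(sam$step)
  tibble::tibble(contraction_pct = contraction,
                 internal_stress_gpa = mean(sam$stress_gpa[keep]))
}

#' Density-normalized toughness and strength
#'
#' Divides toughness and ultimate stress by the fibril mass density relative
#' to the unmineralized (collagen-only) fibril; volumes cancel under the
#' constant-diameter convention.
#'
#' @param summary a `mech_summary` (or list with `toughness_gpa`,
#'   `sigma_max_gpa`).
#' @param model the mineralized `fibril_model` the summary describes.
#' @return tibble: `relative_density`, `toughness_per_density`,
#'   `strength_per_density`.
#' @export
density_normalized_performance <- function(summary, model) {
  mass_tot <- sum(model$beads$mass)
  mass_coll <- sum(model$beads$mass[model$beads$species == "collagen"])
  rel <- mass_tot / mass_coll
  tibble::tibble(relative_density = rel,
                 toughness_per_density = summary$toughness_gpa / rel,
                 strength_per_density = summary$sigma_max_gpa / rel)
}

#' Mechanical summary of a tensile test
#'
#' @param curve a `stress_strain_curve` in the relaxed-length convention.
#' @param contraction_pct optional contraction (%).
#' @param internal_stress_gpa optional internal stress at L0 (GPa).
#' @return a `mech_summary` list: `sigma_max_gpa`, `eps_max` (relaxed
#'   convention), `eps_max_fixed_L0` (when lengths stored), `toughness_gpa`,
#'   `contraction_pct`, `internal_stress_gpa`.
#' @export
mechanical_summary <- function(curve, contraction_pct = NA_real_,
                               internal_stress_gpa = NA_real_) {
  iu <- ultimate_index(curve)
  Lr <- attr(curve, "L_relaxed"); L0 <- attr(curve, "L0")
  eps <- curve$strain[iu]
  eps_fixed <- if (!is.na(Lr) && !is.na(L0)) (Lr / L0) * (1 + eps) - 1
               else NA_real_
  structure(list(sigma_max_gpa = curve$stress[iu],
                 eps_max = eps, eps_max_fixed_L0 = eps_fixed,
                 toughness_gpa = toughness(curve),
                 contraction_pct = contraction_pct,
                 internal_stress_gpa = internal_stress_gpa),
            class = "mech_summary")
}

#' @export
print.mech_summary <- function(x, ...) {
  cat("<mech_summary> sigma_max =", signif(x$sigma_max_gpa, 4),
      "GPa at strain", signif(x$eps_max, 4),
      "; toughness =", signif(x$toughness_gpa, 4), "GPa\n")
  invisible(x)
}

#' Tidy a mechanical summary into one row per quantity
#' @param x a `mech_summary`.
#' @param ... unused.
#' @return tibble with `quantity`, `value`, `units`.
#' @export
tidy.mech_summary <- function(x, ...) {
  tibble::tibble(
    quantity = c("sigma_max", "eps_max", "eps_max_fixed_L0", "toughness",
                 "contraction", "internal_stress"),
    value = c(x$sigma_max_gpa, x$eps_max, x$eps_max_fixed_L0,
              x$toughness_gpa, x$contraction_pct, x$internal_stress_gpa),
    units = c("GPa", "fraction", "fraction", "GPa", "%", "GPa"))
}

#' One-row overview of a mechanical summary
#' @param x a `mech_summary`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
glance.mech_summary <- function(x, ...) {
  tibble::tibble(sigma_max_gpa = x$sigma_max_gpa, eps_max = x$eps_max,
                 toughness_gpa = x$toughness_gpa,
                 contraction_pct = x$contraction_pct,
                 internal_stress_gpa = x$internal_stress_gpa)
}

#' Tidy a regime report (one row per segment)
#' @param x a `regime_report`.
#' @param ... unused.
#' @return the segments tibble.
#' @export
tidy.regime_report <- function(x, ...) x$segments

#' One-row overview of a regime report
#' @param x a `regime_report`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
glance.regime_report <- function(x, ...) {
  tibble::tibble(n_regimes = nrow(x$segments), toe_extent = x$toe_extent,
                 has_sawtooth = x$has_sawtooth, partial = x$partial)
}

#' Plot a stress-strain curve
#'
#' @param object a `stress_strain_curve`.
#' @param regimes optional `regime_report` whose breakpoints are drawn.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.stress_strain_curve <- function(object, regimes = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$strain, .data$stress)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "engineering strain", y = "axial stress (GPa)") +
    ggplot2::theme_minimal()
  if (!is.null(regimes) && length(regimes$breakpoints) > 0)
    p <- p + ggplot2::geom_vline(xintercept = regimes$breakpoints,
                                 linetype = "dashed", colour = "grey50")
  p
}

#' Plot a mineral-density sweep of mechanical summaries
#'
#' @param sweep tibble with a `mineral_wt_pct` column and one or more
#'   response columns.
#' @param response name of the response column.
#' @return a ggplot object.
#' @export
plot_density_sweep <- function(sweep, response = "sigma_max_gpa") {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$mineral_wt_pct,
                                      .data[[response]])) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "mineral density (wt%)", y = response) +
    ggplot2::theme_minimal()
}
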