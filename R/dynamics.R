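# Dynamics: engine state, Maxwell-Boltzmann initialization, equilibration
# with axial box relaxation, and strain-controlled tensile tests.

#' Create an engine state
#'
#' @param model a `fibril_model`.
#' @param config an [engine_config()].
#' @return an `engine_state` list holding the model, simulation clock and
#'   the configuration.
#' @export
engine_state <- function(model, config = engine_config()) {
  structure(list(model = model, config = config, time = 0, step = 0L,
                 run_count = 0L), class = "engine_state")
}

#' @export
print.engine_state <- function(x, ...) {
  cat("<engine_state> t =", x$time / 1e6, "ns, step", x$step, "\n")
  print(x$model)
  invisible(x)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Per-component Gaussian velocities at temperature `T` with the
#' centre-of-mass momentum removed; deterministic given the seed.
#'
#' @param state an `engine_state` (or a `fibril_model`).
#' @param T temperature in K.
#' @param seed integer seed.
#' @return the input with velocities set.
#' @export
initialize_velocities <- function(state, T = 300, seed = 1L) {
  model <- if (inherits(state, "engine_state")) state$model else state
  u <- mcf_units()
  n <- nrow(model$beads)
  if (T <= 0) {
    model$beads$vx <- model$beads$vy <- model$beads$vz <- rep(0, n)
  } else {
    sd <- sqrt(u$kB * T * u$acc_factor / model$beads$mass)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    v <- matrix(stats::rnorm(3 * n), n, 3) * sd
    # remove centre-of-mass momentum
    p <- colSums(v * model$beads$mass)
    v <- sweep(v, 2, p / sum(model$beads$mass))
    model$beads$vx <- v[, 1]; model$beads$vy <- v[, 2]; model$beads$vz <- v[, 3]
  }
  if (inherits(state, "engine_state")) { state$model <- model; state }
  else model
}

#' Kinetic temperature of a state
#' @param model a `fibril_model`.
#' @return temperature in K (3N degrees of freedom convention).
#' @export
kinetic_temperature <- function(model) {
  u <- mcf_units()
  b <- model$beads
  ke <- 0.5 * sum(b$mass * (b$vx^2 + b$vy^2 + b$vz^2)) / u$acc_factor
  2 * ke / (3 * nrow(b) * u$kB)
}

# shared driver over the compiled integrator
run_engine <- function(state, n_steps, thermostat = TRUE, barostat = FALSE,
                       pull_rate_m_s = 0, sample_every = 0, frame_every = 0,
                       kinetic_stress = TRUE, allow_breaking = TRUE) {
  cfg <- state$config
  model <- state$model
  sys <- model_to_sys(model, skin = cfg$neighbor_skin, shift_lj = cfg$shift_lj)
  # volume convention: pi (d/2)^2 per box length for fibrils (d constant),
  # molecule cross-section area for chain fixtures
  vol_factor <- model$registry$volume_factor %||%
    (pi * ((model$registry$diameter_nm %||% 20) * 10 / 2)^2)
  run_seed <- cfg$seed + 1000003L * state$run_count
  res <- cpp_run(sys, as.integer(n_steps), cfg$timestep,
                 cfg$temperature, cfg$damping, thermostat,
                 barostat, cfg$barostat_tau, cfg$barostat_modulus,
                 pull_rate_m_s * 1e-5, vol_factor,
                 as.integer(sample_every), as.integer(frame_every),
                 kinetic_stress, run_seed, allow_breaking)
  model$beads$x <- res$pos[, 1]; model$beads$y <- res$pos[, 2]
  model$beads$z <- res$pos[, 3]
  model$beads$vx <- res$vel[, 1]; model$beads$vy <- res$vel[, 2]
  model$beads$vz <- res$vel[, 3]
  model$bonds$broken <- as.logical(res$broken)
  model$box$length[1] <- res$Lx
  state$model <- model
  state$time <- state$time + n_steps * cfg$timestep
  state$step <- state$step + as.integer(n_steps)
  state$run_count <- state$run_count + 1L
  samp <- res$samples[seq_len(res$n_samples), , drop = FALSE]
  colnames(samp) <- c("step", "time_fs", "Lx", "stress_gpa",
                      "stress_mineral_gpa", "temperature", "E_bond",
                      "E_angle", "E_lj_coll", "E_lj_min", "E_lj_inter",
                      "n_broken", "kinetic", "rmsd")
  list(state = state, samples = tibble::as_tibble(samp),
       frames = res$frames, Lx_start = res$Lx_start)
}

#' Advance the state by a number of velocity-Verlet steps
#'
#' One thermostated velocity-Verlet step (or several) with bond breaking
#' and the axial periodic wrap; neighbour-list rebuilds are triggered by
#' bead displacement, never silently skipped.
#'
#' @param state an `engine_state`.
#' @param n_steps number of steps.
#' @param thermostat logical; `FALSE` gives plain NVE integration.
#' @return the advanced `engine_state`.
#' @export
step_engine <- function(state, n_steps = 1, thermostat = TRUE) {
  run_engine(state, n_steps, thermostat = thermostat)$state
}

#' Equilibrate a fibril with axial box relaxation
#'
#' Langevin thermostat at the configured temperature plus a Berendsen-style
#' relaxation of the axial box length toward zero axial virial stress.
#' Convergence is declared when the positional root-mean-square displacement
#' levels off (relative drift of the RMSD over the last quarter below
#' `rmsd_tol`).
#'
#' @param state an `engine_state`.
#' @param duration_ns duration in ns.
#' @param sample_every sampling stride in steps.
#' @param rmsd_tol relative RMSD drift defining convergence.
#' @return a list: `state` (equilibrated), `report` (tibble of samples),
#'   `converged`, `L_final`, `contraction_pct` (vs the starting length).
#' @export
equilibrate <- function(state, duration_ns = 1, sample_every = 500,
                        rmsd_tol = 0.15) {
  n_steps <- round(duration_ns * 1e6 / state$config$timestep)
  L0 <- state$model$box$length[1]
  res <- run_engine(state, n_steps, thermostat = TRUE,
                    barostat = state$config$barostat == "axial",
                    sample_every = sample_every)
  rep <- res$samples
  nq <- nrow(rep)
  last_q <- rep$rmsd[rep$step >= 0.75 * n_steps]
  converged <- length(last_q) >= 2 &&
    abs(last_q[length(last_q)] - last_q[1]) <=
      rmsd_tol * max(mean(last_q), 1e-9)
  st <- res$state
  st$model$registry$equilibrated <- TRUE
  st$model$registry$L_relaxed <- st$model$box$length[1]
  list(state = st, report = rep, converged = converged,
       L_final = st$model$box$length[1],
       contraction_pct = 100 * (L0 - st$model$box$length[1]) / L0)
}

#' Strain-controlled tensile test
#'
#' Increases the axial box length at a constant displacement rate with an
#' affine remap of bead coordinates each step (barostat off), sampling the
#' axial virial stress, energy terms and broken-bond count.
#'
#' @param state an (equilibrated) `engine_state`.
#' @param rate displacement rate in m/s.
#' @param max_strain engineering strain at which to stop, relative to the
#'   box length at the start of the pull.
#' @param sample_every sampling stride in steps.
#' @param frame_every trajectory frame stride in steps (0 = none).
#' @return a list: `state`, `curve` (a [stress_strain_curve()] tibble),
#'   `samples` (raw tibble), `frames`.
#' @export
run_tensile_test <- function(state, rate = NULL, max_strain = 1,
                             sample_every = 200, frame_every = 0) {
  cfg <- state$config
  rate <- rate %||% cfg$pull_rate
  L0 <- state$model$box$length[1]
  dL_step <- rate * 1e-5 * cfg$timestep
  if (dL_step > 0.05 * L0)
    stop("run_tensile_test: per-step strain ", signif(dL_step / L0, 3),
         " exceeds the stability bound; lower the rate")
  n_steps <- if (rate > 0) ceiling(max_strain * L0 / dL_step) else
    ceiling(max_strain * 1e5)
  res <- run_engine(state, n_steps, thermostat = TRUE, barostat = FALSE,
                    pull_rate_m_s = rate, sample_every = sample_every,
                    frame_every = frame_every)
  samples <- res$samples
  samples$strain <- samples$Lx / L0 - 1
  L_unmin <- state$model$registry$L_unmineralized %||% L0
  curve <- stress_strain_curve(samples$strain, samples$stress_gpa,
                               L_relaxed = L0, L0 = L_unmin)
  list(state = res$state, curve = curve, samples = samples,
       frames = res$frames)
}
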