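# Dispatch a Langevin run to the compiled kernel (native backends) or the
# generic R loop.  `pull` is NULL or list(atom_row, direction, k [kcal/mol/A^2],
# velocity [A/ps]); `record_rows` are atom rows snapshotted every
# `sample_every` steps; `movable_override` (logical) is intersected with the
# backend mask.
langevin_run <- function(backend, positions, velocities, spec, n_steps,
                         external_force = NULL, pull = NULL,
                         sample_every = 0, record_rows = integer(0),
                         movable_override = NULL) {
  n <- nrow(positions)
  stopifnot(inherits(backend, "ff_backend"), length(backend$masses) == n)
  movable <- backend$movable_mask
  if (!is.null(movable_override)) movable <- movable & movable_override
  if (!is.null(spec$seed)) set.seed(spec$seed)
  dt <- spec$timestep_fs / 1000
  kT <- .kB * spec$temperature_K
  ext <- if (is.null(external_force)) matrix(0, 0, 3) else as.matrix(external_force)

  nat <- backend$native
  if (!is.null(nat) && nat$type %in% c("none", "harmonic", "enm")) {
    ff_type <- match(nat$type, c("none", "harmonic", "enm")) - 1L
    out <- integrate_langevin_cpp(
      ff_type, positions, velocities, backend$masses, movable,
      if (ff_type == 1) nat$k else numeric(n),
      if (ff_type == 1) nat$ref else matrix(0, n, 3),
      if (ff_type == 2) as.integer(nat$pairs_i) else integer(0),
      if (ff_type == 2) as.integer(nat$pairs_j) else integer(0),
      if (ff_type == 2) nat$k else numeric(0),
      if (ff_type == 2) nat$d0 else numeric(0),
      dt, spec$friction_ps, kT, as.integer(n_steps), ext,
      !is.null(pull), if (is.null(pull)) 1L else as.integer(pull$atom_row),
      if (is.null(pull)) c(0, 0, 1) else pull$direction,
      if (is.null(pull)) 0 else pull$k,
      if (is.null(pull)) 0 else pull$velocity,
      as.integer(sample_every), as.integer(record_rows))
    if (sample_every > 0) {
      ns <- out$n_samples
      if (nrow(out$samples) > ns) out$samples <- out$samples[seq_len(ns), , drop = FALSE]
      if (nrow(out$traj) > ns) out$traj <- out$traj[seq_len(ns), , drop = FALSE]
    }
    return(out)
  }
  langevin_run_r(backend, positions, velocities, movable, dt,
                 spec$friction_ps, kT, n_steps, ext, pull,
                 sample_every, record_rows)
}

# Generic pure-R BAOAB loop over backend$evaluate(); the reference
# implementation for the external-engine adapter route.
langevin_run_r <- function(backend, x, v, movable, dt, gamma, kT, n_steps,
                           ext, pull, sample_every, record_rows) {
  n <- nrow(x)
  m <- backend$masses
  c1 <- exp(-gamma * dt)
  sig <- sqrt(kT * .kcal_to_akma * (1 - c1^2) / m)
  half <- dt / 2
  x0_proj <- if (!is.null(pull)) sum(x[pull$atom_row, ] * pull$direction) else 0
  spring_force <- function(t) {
    proj <- sum(x[pull$atom_row, ] * pull$direction)
    pull$k * (pull$velocity * t - (proj - x0_proj))
  }
  bias <- function(f, t) {
    if (nrow(ext) == n) f <- f + ext
    if (!is.null(pull)) {
      f[pull$atom_row, ] <- f[pull$atom_row, ] + spring_force(t) * pull$direction
    }
    f
  }
  samples <- NULL; traj <- NULL
  if (sample_every > 0) {
    ns <- n_steps %/% sample_every + 1
    if (!is.null(pull)) samples <- matrix(0, ns, 2)
    if (length(record_rows)) traj <- matrix(0, ns, 3 * length(record_rows))
  }
  si <- 0
  record <- function(t) {
    si <<- si + 1
    if (!is.null(samples)) samples[si, ] <<- c(pull$velocity * t, spring_force(t))
    if (!is.null(traj)) traj[si, ] <<- as.numeric(t(x[record_rows, , drop = FALSE]))
  }
  f <- bias(backend$evaluate(x)$forces, 0)
  if (sample_every > 0) record(0)
  invm <- .kcal_to_akma / m
  for (step in seq_len(n_steps)) {
    t1 <- step * dt
    v[movable, ] <- v[movable, ] + half * f[movable, , drop = FALSE] * invm[movable]
    x[movable, ] <- x[movable, ] + half * v[movable, , drop = FALSE]
    if (gamma > 0 || kT > 0) {
      noise <- matrix(stats::rnorm(3 * n), n, 3) * sig
      v[movable, ] <- c1 * v[movable, , drop = FALSE] + noise[movable, , drop = FALSE]
    }
    x[movable, ] <- x[movable, ] + half * v[movable, , drop = FALSE]
    f <- bias(backend$evaluate(x)$forces, t1)
    v[movable, ] <- v[movable, ] + half * f[movable, , drop = FALSE] * invm[movable]
    if (sample_every > 0 && step %% sample_every == 0) record(t1)
    if (!all(is.finite(x))) stop("numerical blow-up at step ", step)
  }
  list(x = x, v = v,
       samples = if (is.null(samples)) matrix(0, 0, 2) else samples[seq_len(si), , drop = FALSE],
       traj = if (is.null(traj)) matrix(0, 0, 0) else traj[seq_len(si), , drop = FALSE],
       n_samples = si)
}

#' Advance a system by Langevin dynamics
#'
#' Thermostatted BAOAB integration under the backend's force field plus an
#' optional constant per-atom external force.  Atoms masked off in the
#' backend's `movable_mask` never move.  Runs are reproducible given
#' `spec$seed`; at zero temperature and friction the scheme reduces to
#' velocity Verlet.
#'
#' @param backend a [ff_backend()].
#' @param positions n x 3 matrix (A).
#' @param velocities n x 3 matrix (A/ps); zeros if omitted.
#' @param spec an [integrator_spec()].
#' @param external_force optional n x 3 matrix of constant forces
#'   (kcal/mol/A).
#' @param n_steps number of timesteps.
#' @return list with updated `positions` and `velocities`.
#' @export
step_langevin <- function(backend, positions, velocities = NULL, spec,
                          external_force = NULL, n_steps) {
  positions <- as.matrix(positions)
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  out <- langevin_run(backend, positions, as.matrix(velocities), spec,
                      n_steps, external_force = external_force)
  list(positions = out$x, velocities = out$v)
}

# thermal velocities for movable atoms (Maxwell-Boltzmann)
draw_velocities <- function(backend, temperature_K) {
  n <- length(backend$masses)
  sig <- sqrt(.kB * temperature_K * .kcal_to_akma / backend$masses)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sig
  v[!backend$movable_mask, ] <- 0
  v
}
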