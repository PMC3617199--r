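#' Equilibrate a structure under a backend
#'
#' Energy-minimizes the movable atoms (T = 0), then runs thermostatted
#' Langevin dynamics through a schedule of stages with stepwise release of
#' spatial constraints: each stage immobilizes a selection ("all",
#' "backbone", "none", or an atom-id vector) for a given duration.  Mutant
#' re-equilibration appends an extra unconstrained stage.
#'
#' @param structure a [mol_structure()].
#' @param backend a [ff_backend()].
#' @param schedule list of `list(restrain =, duration_ps =)` stages, applied
#'   in order.
#' @param spec an [integrator_spec()].
#' @param minimize run the T = 0 minimization first (default TRUE).
#' @return the structure with equilibrated coordinates.
#' @export
equilibrate <- function(structure, backend,
                        schedule = list(list(restrain = "all", duration_ps = 100),
                                        list(restrain = "backbone", duration_ps = 100)),
                        spec = integrator_spec(), minimize = TRUE) {
  xyz <- coords(structure)
  n <- nrow(xyz)
  if (minimize) {
    mov <- backend$movable_mask
    if (any(mov)) {
      par0 <- as.numeric(xyz[mov, ])
      fn <- function(p) {
        xx <- xyz; xx[mov, ] <- matrix(p, ncol = 3)
        backend$evaluate(xx)$energy
      }
      gr <- function(p) {
        xx <- xyz; xx[mov, ] <- matrix(p, ncol = 3)
        -as.numeric(backend$evaluate(xx)$forces[mov, ])
      }
      opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                          control = list(maxit = 500))
      xyz[mov, ] <- matrix(opt$par, ncol = 3)
    }
  }
  vel <- matrix(0, n, 3)
  for (k in seq_along(schedule)) {
    stage <- schedule[[k]]
    if (stage$duration_ps <= 0) next
    restrained <- stage_restraint_rows(structure, stage$restrain)
    override <- rep(TRUE, n)
    override[restrained] <- FALSE
    n_steps <- max(1L, round(stage$duration_ps / (spec$timestep_fs / 1000)))
    out <- tryCatch(
      langevin_run(backend, xyz, vel, spec, n_steps,
                   movable_override = override),
      error = function(e) {
        stop("equilibration stage ", k, " (restrain = ",
             paste(stage$restrain, collapse = ","), ") failed: ",
             conditionMessage(e))
      })
    xyz <- out$x
    vel <- out$v
    spec$seed <- NULL  # reseeding each stage would replay the same noise
  }
  set_coords(structure, xyz)
}

stage_restraint_rows <- function(structure, restrain) {
  if (is.character(restrain) && length(restrain) == 1) {
    switch(restrain,
      all = seq_len(nrow(structure$atoms)),
      backbone = which(structure$atoms$atom_name %in% c("N", "CA", "C", "O")),
      none = integer(0),
      stop("unknown restraint selection: ", restrain))
  } else {
    match(restrain, structure$atoms$atom_id)
  }
}

#' Run one constant-velocity pull
#'
#' The dummy atom starts at the SMD atom's position and moves along the pull
#' direction at constant velocity; the SMD atom is coupled to it by a
#' harmonic spring acting along that direction.  Atoms in the free zone
#' move under the backend's forces; fixed-shell CA atoms are immobile;
#' remaining atoms move freely.  No pre-pull minimization is done: pulling
#' starts from the equilibrated configuration as-is, with the spring
#' relaxed.  Sampling every `sample_every` steps yields the force-extension
#' trace, stopping when the dummy displacement reaches the configured
#' maximum.
#'
#' @param structure a [mol_structure()] (equilibrated).
#' @param pull_spec a [build_pull_spec()] object.
#' @param backend a [ff_backend()].
#' @param seed RNG seed for the thermostat.
#' @param spec an [integrator_spec()]; its temperature is overridden by the
#'   pull spec's.
#' @param sample_every sampling interval in integrator steps (default 10).
#' @param freeze_outside also freeze non-CA atoms outside the free zone
#'   (default FALSE: they are unrestrained).
#' @return an object of class `fe_trace` with a `samples` data.frame
#'   (`displacement` A, `force_pN`).
#' @export
run_smd <- function(structure, pull_spec, backend, seed = 1,
                    spec = integrator_spec(), sample_every = 10,
                    freeze_outside = FALSE) {
  stopifnot(inherits(pull_spec, "pull_spec"))
  xyz <- coords(structure)
  n <- nrow(xyz)
  spec$temperature_K <- pull_spec$temperature
  spec$seed <- seed
  override <- rep(TRUE, n)
  fixed_rows <- match(pull_spec$fixed_ca_ids, structure$atoms$atom_id)
  override[fixed_rows] <- FALSE
  if (freeze_outside) {
    free_rows <- match(pull_spec$free_atom_ids, structure$atoms$atom_id)
    outside <- setdiff(seq_len(n), free_rows)
    override[outside] <- FALSE
  }
  dt <- spec$timestep_fs / 1000
  n_steps <- ceiling(pull_spec$max_dummy_displacement /
                       (pull_spec$pull_velocity * dt))
  pull <- list(atom_row = atom_row(structure, pull_spec$smd_atom_id),
               direction = pull_spec$direction,
               k = pull_spec$spring_constant,
               velocity = pull_spec$pull_velocity)
  out <- langevin_run(backend, xyz, matrix(0, n, 3), spec, n_steps,
                      pull = pull, sample_every = sample_every,
                      movable_override = override)
  samples <- data.frame(displacement = out$samples[, 1],
                        force_pN = out$samples[, 2] * .pn_per_kcal_mol_ang)
  keep <- samples$displacement <= pull_spec$max_dummy_displacement + 1e-9
  structure(list(residue_index = pull_spec$residue_index,
                 replicate_seed = seed,
                 samples = samples[keep, ],
                 sampling_interval = sample_every,
                 pull_spec = pull_spec,
                 final_positions = out$x),
            class = "fe_trace")
}

#' @export
print.fe_trace <- function(x, ...) {
  cat(sprintf("<fe_trace> residue %d, seed %s, %d samples to %.2f A\n",
              x$residue_index, format(x$replicate_seed), nrow(x$samples),
              max(x$samples$displacement)))
  invisible(x)
}

#' Repeat a pull with independent thermostat seeds
#'
#' Replicates differ only by the thermostat seed (`seed_base` + replicate
#' index).  Twelve replicates is the protocol's reference count; fewer
#' triggers a warning.
#'
#' @inheritParams run_smd
#' @param n_replicates number of replicates (warn below 12).
#' @param seed_base base seed.
#' @return list of `fe_trace` objects.
#' @export
run_replicates <- function(structure, pull_spec, backend, n_replicates = 12,
                           seed_base = 0, spec = integrator_spec(),
                           sample_every = 10, freeze_outside = FALSE) {
  stopifnot(n_replicates >= 1)
  if (n_replicates < 12) {
    warning("protocol reference is at least 12 replicates; running ",
            n_replicates)
  }
  lapply(seq_len(n_replicates), function(i) {
    run_smd(structure, pull_spec, backend, seed = seed_base + i,
            spec = spec, sample_every = sample_every,
            freeze_outside = freeze_outside)
  })
}

#' Pull every surface residue
#'
#' For each residue selected in the surface set, builds the pull
#' specification (outward direction and mobile/fixed partition) from the
#' supplied structure and runs the replicate pulls.  Residues whose pulling
#' direction is degenerate (symmetric neighbourhoods) are skipped, recorded
#' in the `failures` attribute, and the scan continues.
#'
#' @param structure equilibrated [mol_structure()].
#' @param surface_set a `surface_set` from [select_surface_residues()].
#' @param protocol_config list of protocol parameters; see
#'   [default_protocol_config()].
#' @param backend a [ff_backend()].
#' @return named list: residue index -> list of `fe_trace`; failures (if
#'   any) in `attr(, "failures")`.
#' @export
scan_surface <- function(structure, surface_set, protocol_config = default_protocol_config(),
                         backend) {
  if (length(surface_set$selected) == 0) stop("surface set is empty")
  cfg <- utils::modifyList(default_protocol_config(), protocol_config)
  spec <- integrator_spec(cfg$timestep_fs, cfg$friction_ps, cfg$temperature)
  results <- list()
  failures <- list()
  for (r in surface_set$selected) {
    ps <- tryCatch(
      build_pull_spec(structure, r,
                      spring_constant = cfg$spring_constant,
                      pull_velocity = cfg$pull_velocity,
                      max_dummy_displacement = cfg$max_dummy_displacement,
                      temperature = cfg$temperature,
                      neighborhood_radius = cfg$neighborhood_radius,
                      free_radius = cfg$free_radius),
      error = function(e) e)
    if (inherits(ps, "error")) {
      failures[[as.character(r)]] <- conditionMessage(ps)
      next
    }
    traces <- withCallingHandlers(
      run_replicates(structure, ps, backend,
                     n_replicates = cfg$n_replicates,
                     seed_base = residue_seed_base(cfg$seed_base, r),
                     spec = spec, sample_every = cfg$sample_every,
                     freeze_outside = cfg$freeze_outside),
      warning = function(w) invokeRestart("muffleWarning"))
    results[[as.character(r)]] <- traces
  }
  if (length(failures) > 0) attr(results, "failures") <- failures
  results
}

# Reproducible per-residue seed stream: seed_base*1e6 + residue*100 keeps
# replicate seeds disjoint across residues; wrapped into 32-bit range.
residue_seed_base <- function(seed_base, residue_index) {
  (seed_base * 1e6 + residue_index * 100) %% 2147483647
}

#' Default pulling-protocol parameters
#'
#' One place for the protocol constants: SASA threshold 30 A^2, 4 A
#' direction neighbourhood, 13 A free zone, 7 kcal/mol/A^2 spring,
#' 0.15 A/ps pull velocity, 2.5 A pull length and fit range, >= 12
#' replicates, 310 K, classification thresholds 100/300 pN/A and delta
#' threshold 70 pN/A.
#'
#' @return named list of parameters.
#' @export
default_protocol_config <- function() {
  list(
    sasa_threshold = 30,        # A^2, surface-residue selection
    probe_radius = 1.4,         # A, water probe
    n_sphere_points = 960,
    neighborhood_radius = 4,    # A, pulling-direction neighbourhood
    free_radius = 13,           # A, mobile zone around the SMD atom
    spring_constant = 7,        # kcal/mol/A^2, virtual spring
    pull_velocity = 0.15,       # A/ps, constant dummy velocity
    max_dummy_displacement = 2.5,  # A, pull length
    fit_range = 2.5,            # A, regression window
    n_replicates = 12,
    temperature = 310,          # K
    timestep_fs = 2,
    friction_ps = 1,
    sample_every = 10,
    class_low = 100,            # pN/A, "mobile" threshold
    class_high = 300,           # pN/A, "static" threshold
    delta_threshold = 70,       # pN/A, conformation-pair change threshold
    patch_linkage_cutoff = 8,   # A, CA-CA patch linkage
    patch_min_size = 2,
    freeze_outside = FALSE,
    seed_base = 1
  )
}

#' Export a force-extension trace as TSV text
#'
#' @param trace an `fe_trace`.
#' @return character scalar (columns displacement_A, force_pN).
#' @export
trace_tsv <- function(trace) {
  paste(c("displacement_A\tforce_pN",
          sprintf("%.6f\t%.6f", trace$samples$displacement,
                  trace$samples$force_pN), ""),
        collapse = "\n")
}
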