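#' Force-field backend contract
#'
#' A `ff_backend` is the engine-agnostic surface the pulling and equilibrium
#' protocols run on.  It carries:
#' \itemize{
#'   \item `evaluate(positions)`: n_atoms x 3 matrix -> list(energy
#'     [kcal/mol], forces [n x 3, kcal/mol/A]); forces are the negative
#'     gradient of the energy.
#'   \item `movable_mask`: logical per atom; masked-off atoms never move.
#'   \item `masses`: amu per atom.
#'   \item `native`: optional descriptor (`type` = "harmonic"/"enm"/"none"
#'     plus parameters) that the compiled integrator dispatches on; backends
#'     without one fall back to a pure-R integration loop, which is also the
#'     route an external all-atom engine adapter would take (initialize from
#'     a `mol_structure` and a `pull_spec`, run, return a force-extension
#'     trace).
#' }
#'
#' @param name backend name.
#' @param evaluate energy/force closure as described above.
#' @param movable_mask logical vector per atom.
#' @param masses numeric vector, amu per atom.
#' @param params named list of backend parameters.
#' @param native optional native-dispatch descriptor.
#' @return an object of class `ff_backend`.
#' @export
ff_backend <- function(name, evaluate, movable_mask, masses, params = list(),
                       native = NULL) {
  stopifnot(is.function(evaluate), is.logical(movable_mask),
            length(masses) == length(movable_mask), all(masses > 0))
  structure(list(name = name, evaluate = evaluate,
                 movable_mask = movable_mask, masses = masses,
                 params = params, native = native),
            class = "ff_backend")
}

#' @export
print.ff_backend <- function(x, ...) {
  cat(sprintf("<ff_backend> %s: %d atoms (%d movable)%s\n", x$name,
              length(x$movable_mask), sum(x$movable_mask),
              if (is.null(x$native)) " [generic]" else ""))
  invisible(x)
}

#' Independent harmonic-tether toy backend
#'
#' Each bead is tethered to its reference position by an isotropic spring:
#' E = sum_i k_i/2 |r_i - r_i0|^2.  Because the beads are independent, the
#' resistance coefficient of a pulled bead has the closed form
#' k_t * k_p / (k_t + k_p) (tether and pulling spring in series), which makes
#' this backend the analytic oracle for the whole pipeline.
#'
#' @param tether_stiffness tether spring constant(s) in pN/A, scalar or one
#'   per bead; 0 gives a free particle.
#' @param reference_positions n x 3 matrix of tether anchor points.
#' @param masses bead masses in amu (default 100).
#' @return a [ff_backend()].
#' @export
build_harmonic_toy_backend <- function(tether_stiffness, reference_positions,
                                       masses = 100) {
  ref <- as.matrix(reference_positions)
  if (ncol(ref) != 3) stop("reference_positions must be n x 3")
  n <- nrow(ref)
  stopifnot(all(tether_stiffness >= 0))
  k_pn <- rep(tether_stiffness, length.out = n)
  k <- k_pn / .pn_per_kcal_mol_ang          # kcal/mol/A^2
  masses <- rep(masses, length.out = n)
  evaluate <- function(positions) {
    dx <- positions - ref
    list(energy = sum(0.5 * k * rowSums(dx^2)),
         forces = -dx * k)
  }
  ff_backend("harmonic_toy", evaluate,
             movable_mask = rep(TRUE, n), masses = masses,
             params = list(tether_stiffness_pn = k_pn),
             native = list(type = "harmonic", k = k, ref = ref))
}

#' Elastic-network backend over heavy atoms
#'
#' Hookean springs connect every heavy-atom pair closer than `cutoff` in the
#' reference structure: E = sum_pairs k/2 (d - d0)^2.  Region-specific
#' stiffness multipliers (applied when both endpoints belong to the
#' override's atom set) let fixtures emulate, e.g., ligand-induced local
#' stiffening of a binding site.
#'
#' @param structure a [mol_structure()] giving the reference geometry.
#' @param params list with `cutoff` (A, default 10), `spring` (kcal/mol/A^2,
#'   default 1), and optional `overrides` = list of
#'   `list(atom_ids =, multiplier =)`.
#' @param masses optional per-atom masses (amu); defaults to element masses.
#' @return a [ff_backend()].
#' @export
build_enm_backend <- function(structure, params = list(), masses = NULL) {
  cutoff <- params$cutoff %||% 10
  spring <- params$spring %||% 1
  stopifnot(cutoff > 0, spring > 0)
  a <- structure$atoms
  heavy <- toupper(a$element) != "H"
  if (sum(heavy) < 2) stop("elastic network needs at least 2 heavy atoms")
  xyz <- coords(structure)
  dm <- as.matrix(stats::dist(xyz[heavy, , drop = FALSE]))
  hidx <- which(heavy)
  pr <- which(upper.tri(dm) & dm <= cutoff, arr.ind = TRUE)
  if (nrow(pr) == 0) stop("no atom pairs within cutoff ", cutoff, " A")
  pi_ <- hidx[pr[, 1]]
  pj_ <- hidx[pr[, 2]]
  d0 <- dm[pr]
  kp <- rep(spring, length(d0))
  for (ov in params$overrides %||% list()) {
    rows <- match(ov$atom_ids, a$atom_id)
    if (anyNA(rows)) stop("override names unknown atom ids")
    inset <- pi_ %in% rows & pj_ %in% rows
    kp[inset] <- kp[inset] * ov$multiplier
  }
  g <- igraph::graph_from_edgelist(cbind(match(pi_, hidx), match(pj_, hidx)),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(hidx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    sizes <- paste(comp$csize, collapse = ", ")
    stop("elastic network is disconnected under cutoff ", cutoff,
         " A: component sizes ", sizes)
  }
  n <- nrow(a)
  masses <- rep(masses %||% element_masses(structure), length.out = n)
  movable <- rep(TRUE, n)
  movable[!heavy] <- FALSE   # hydrogens carry no network springs
  evaluate <- function(positions) {
    dvec <- positions[pi_, , drop = FALSE] - positions[pj_, , drop = FALSE]
    d <- sqrt(rowSums(dvec^2))
    stretch <- d - d0
    e <- sum(0.5 * kp * stretch^2)
    fmag <- -kp * stretch / d
    fv <- dvec * fmag
    fx <- rowsum(rbind(fv, -fv), c(pi_, pj_))
    forces <- matrix(0, n, 3)
    forces[as.integer(rownames(fx)), ] <- fx
    list(energy = e, forces = forces)
  }
  ff_backend("enm", evaluate, movable_mask = movable, masses = masses,
             params = list(cutoff = cutoff, spring = spring,
                           n_pairs = length(d0)),
             native = list(type = "enm", pairs_i = pi_, pairs_j = pj_,
                           k = kp, d0 = d0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Langevin integrator settings
#'
#' BAOAB-scheme Langevin dynamics.  In the zero-temperature, zero-friction
#' limit the scheme reduces to velocity Verlet.
#'
#' @param timestep_fs integration step in femtoseconds (default 2).
#' @param friction_ps friction in 1/ps (default 1).
#' @param temperature_K bath temperature in K (default 310).
#' @param seed optional RNG seed applied before integration.
#' @return an object of class `integrator_spec`.
#' @export
integrator_spec <- function(timestep_fs = 2, friction_ps = 1,
                            temperature_K = 310, seed = NULL) {
  stopifnot(timestep_fs > 0, friction_ps >= 0, temperature_K >= 0)
  structure(list(timestep_fs = timestep_fs, friction_ps = friction_ps,
                 temperature_K = temperature_K, seed = seed),
            class = "integrator_spec")
}
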