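# Bead "residues" are single CA-named carbon atoms so that the whole
# pipeline (SASA, direction, partition, pulling) runs on them unmodified.

bead_atoms <- function(xyz, residue_name = "BEA") {
  n <- nrow(xyz)
  data.frame(atom_id = seq_len(n), atom_name = "CA", element = "C",
             residue_index = seq_len(n), residue_name = residue_name,
             chain_id = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1, bfactor = 0)
}

# CA-like helical curve: ~3.8 A between consecutive beads, gentle curvature
# so the 4 A direction neighbourhood is never symmetric.
helix_curve <- function(n, radius = 2.3, twist_deg = 100, rise = 1.5) {
  i <- seq_len(n) - 1
  th <- i * twist_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), i * rise)
}

# Planar ring with 3.8 A bead spacing: every bead sees an identical local
# geometry (neighbour shells, free zone, fixed anchors), so pulled slopes
# differ only through the spring map -- the property parameter-recovery
# fixtures need.
ring_curve <- function(n, spacing = 3.8) {
  r <- spacing / (2 * sin(pi / n))
  th <- (seq_len(n) - 1) * 2 * pi / n
  cbind(r * cos(th), r * sin(th), rep(0, n))
}

series_slope <- function(k_tether_pn, k_pull_pn) {
  ifelse(k_tether_pn + k_pull_pn > 0,
         k_tether_pn * k_pull_pn / (k_tether_pn + k_pull_pn), 0)
}

#' Generate a synthetic test system with known mechanics
#'
#' Fixture kinds:
#' \describe{
#'   \item{single_bead}{one tethered bead; the fitted resistance coefficient
#'     has the closed form k_t k_p / (k_t + k_p) (springs in series).}
#'   \item{bead_chain}{beads on a CA-like helical curve, each independently
#'     tethered with its own stiffness; per-bead analytic slopes.}
#'   \item{two_region_cluster}{an elastic-network bead wheel (ring plus
#'     central hub) whose first half has its springs multiplied (default
#'     x4); ground truth is the region labels (stiff residues must out-rank
#'     soft ones).  Ring symmetry makes every bead's geometric environment
#'     identical, so pulled slopes reflect the spring map alone.}
#'   \item{ideal_helix_peptide}{all-atom (heavy) poly-alanine alpha helix
#'     built from ideal internal coordinates (phi = -57, psi = -47);
#'     `sequence` may substitute other residue types, which receive a CB+CG
#'     stub side chain.}
#'   \item{hemispherical_shell}{a bead at the apex of a hemispherical shell;
#'     the outward pulling direction is the +z symmetry axis.}
#'   \item{atom_cage}{a bead at the centre of an icosahedral cage: zero
#'     SASA and a degenerate pulling direction.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param ... kind-specific parameters (documented in the source; all have
#'   defaults).
#' @param seed RNG seed for the (rare) randomized parameters.
#' @return list with `structure` ([mol_structure()]), `backend`
#'   ([ff_backend()]) and a machine-readable `ground_truth` list.
#' @export
make_fixture <- function(kind = c("single_bead", "bead_chain",
                                  "two_region_cluster", "ideal_helix_peptide",
                                  "hemispherical_shell", "atom_cage"),
                         ..., seed = 1) {
  kind <- match.arg(kind)
  args <- list(...)
  set.seed(seed)
  switch(kind,
    single_bead = fixture_single_bead(args),
    bead_chain = fixture_bead_chain(args),
    two_region_cluster = fixture_two_region(args),
    ideal_helix_peptide = fixture_helix(args),
    hemispherical_shell = fixture_shell(args),
    atom_cage = fixture_cage(args))
}

fixture_single_bead <- function(args) {
  k_t <- args$tether_stiffness_pn %||% convert_spring_constant(7)
  k_p <- args$pull_spring_pn %||% convert_spring_constant(7)
  xyz <- matrix(0, 1, 3)
  s <- mol_structure(bead_atoms(xyz))
  b <- build_harmonic_toy_backend(k_t, xyz, masses = args$mass %||% 100)
  list(structure = s, backend = b,
       ground_truth = list(kind = "single_bead",
                           tether_stiffness_pn = k_t,
                           pull_spring_pn = k_p,
                           expected_slope_pn = series_slope(k_t, k_p),
                           direction = c(0, 0, 1)))
}

fixture_bead_chain <- function(args) {
  n <- args$n_beads %||% 10
  k_t <- rep(args$tether_stiffness_pn %||% 150, length.out = n)
  k_p <- args$pull_spring_pn %||% convert_spring_constant(7)
  xyz <- helix_curve(n)
  s <- mol_structure(bead_atoms(xyz))
  b <- build_harmonic_toy_backend(k_t, xyz, masses = args$mass %||% 100)
  list(structure = s, backend = b,
       ground_truth = list(kind = "bead_chain",
                           tether_stiffness_pn = k_t,
                           pull_spring_pn = k_p,
                           expected_slopes_pn = series_slope(k_t, k_p)))
}

# Wheel topology: a bead ring plus a central hub bead.  Each bead's radial
# spoke spring dominates its pulled stiffness and is multiplied only by the
# bead's own region membership, so region recovery is not smeared by the
# free-zone window at the region boundary; the hub itself is held rigid by
# its spokes to the fixed far side of the ring.
fixture_two_region <- function(args) {
  n <- args$n_beads %||% 16
  stiff <- args$stiff_residues %||% seq_len(n %/% 2)
  mult <- args$stiff_multiplier %||% 4
  spring <- args$spring %||% 1
  cutoff <- args$cutoff %||% 10
  xyz <- rbind(ring_curve(n), c(0, 0, 0))
  hub <- n + 1L
  s <- mol_structure(bead_atoms(xyz))
  b <- build_enm_backend(
    s, params = list(cutoff = cutoff, spring = spring,
                     overrides = list(list(atom_ids = c(stiff, hub),
                                           multiplier = mult))),
    masses = args$mass %||% 100)
  list(structure = s, backend = b,
       ground_truth = list(kind = "two_region_cluster",
                           stiff_residues = stiff,
                           soft_residues = setdiff(seq_len(n), stiff),
                           hub_residue = hub,
                           stiff_multiplier = mult))
}

fixture_shell <- function(args) {
  r <- args$radius %||% 3
  n_ring <- args$n_ring %||% 8
  polar <- args$polar_deg %||% 60
  ring_angles <- seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
  th <- polar * pi / 180
  ring <- cbind(r * sin(th) * cos(ring_angles),
                r * sin(th) * sin(ring_angles),
                r * cos(th))
  xyz <- rbind(c(0, 0, r), ring)
  s <- mol_structure(bead_atoms(xyz))
  b <- build_harmonic_toy_backend(args$tether_stiffness_pn %||% 100, xyz)
  list(structure = s, backend = b,
       ground_truth = list(kind = "hemispherical_shell", apex_residue = 1L,
                           expected_direction = c(0, 0, 1)))
}

fixture_cage <- function(args) {
  r <- args$radius %||% 2.5
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
             c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
             c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v <- v / sqrt(1 + phi^2) * r
  xyz <- rbind(c(0, 0, 0), v)
  s <- mol_structure(bead_atoms(xyz))
  b <- build_harmonic_toy_backend(args$tether_stiffness_pn %||% 100, xyz)
  list(structure = s, backend = b,
       ground_truth = list(kind = "atom_cage", buried_residue = 1L))
}

# ideal alpha-helix peptide, heavy atoms only
fixture_helix <- function(args) {
  n <- args$n_residues %||% 20
  sequence <- args$sequence %||% rep("ALA", n)
  n <- length(sequence)
  phi <- args$phi %||% -57
  psi <- args$psi %||% -47
  build_helix_peptide(sequence, phi, psi)
}

build_helix_peptide <- function(sequence, phi = -57, psi = -47) {
  place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
    # NeRF: position a new atom given three predecessors + internal coords
    ang <- angle_deg * pi / 180
    tor <- torsion_deg * pi / 180
    bc <- c - b; bc <- bc / sqrt(sum(bc^2))
    ab <- b - a
    nv <- c(ab[2] * bc[3] - ab[3] * bc[2],
            ab[3] * bc[1] - ab[1] * bc[3],
            ab[1] * bc[2] - ab[2] * bc[1])
    nv <- nv / sqrt(sum(nv^2))
    m <- c(nv[2] * bc[3] - nv[3] * bc[2],
           nv[3] * bc[1] - nv[1] * bc[3],
           nv[1] * bc[2] - nv[2] * bc[1])
    d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
    c + d2[1] * bc + d2[2] * m + d2[3] * nv
  }
  rows <- list()
  aid <- 0
  add <- function(name, el, ri, rn, p) {
    aid <<- aid + 1
    rows[[length(rows) + 1]] <<- data.frame(
      atom_id = aid, atom_name = name, element = el, residue_index = ri,
      residue_name = rn, chain_id = "A", x = p[1], y = p[2], z = p[3],
      occupancy = 1, bfactor = 0)
  }
  n_prev <- c(0, 0, 0)
  ca_prev <- c(1.458, 0, 0)
  c_prev <- ca_prev + 1.525 * c(cos((180 - 111.2) * pi / 180),
                                sin((180 - 111.2) * pi / 180), 0)
  for (i in seq_along(sequence)) {
    rn <- toupper(sequence[i])
    if (i == 1) {
      npos <- n_prev; capos <- ca_prev; cpos <- c_prev
    } else {
      npos <- place_atom(n_prev, ca_prev, c_prev, 1.329, 116.2, psi)
      capos <- place_atom(ca_prev, c_prev, npos, 1.458, 121.7, 180)  # omega
      cpos <- place_atom(c_prev, npos, capos, 1.525, 111.2, phi)
    }
    add("N", "N", i, rn, npos)
    add("CA", "C", i, rn, capos)
    add("C", "C", i, rn, cpos)
    # carbonyl O: trans to the next N along the psi torsion
    opos <- place_atom(npos, capos, cpos, 1.231, 120.5, psi + 180)
    add("O", "O", i, rn, opos)
    if (rn != "GLY") {
      cb <- ideal_cb(npos, capos, cpos)
      add("CB", "C", i, rn, cb)
      if (!rn %in% c("ALA", "GLY")) {
        cg <- cb + 1.52 * (cb - capos) / sqrt(sum((cb - capos)^2))
        add("CG", "C", i, rn, cg)
      }
    }
    n_prev <- npos; ca_prev <- capos; c_prev <- cpos
  }
  s <- mol_structure(do.call(rbind, rows))
  b <- build_enm_backend(s, params = list(cutoff = 10, spring = 1))
  list(structure = s, backend = b,
       ground_truth = list(kind = "ideal_helix_peptide",
                           sequence = toupper(sequence), phi = phi, psi = psi))
}

#' Generate a matched two-state (apo/ligand-loaded style) fixture pair
#'
#' Two bead systems with identical topology and coordinates whose tether
#' stiffness differs in one region, emulating ligand-induced stiffening.
#' The state-B stiffness in that region is chosen analytically (by inverting
#' the series-spring formula) so that the expected resistance-coefficient
#' shift equals `delta_target_pn` (default +150 pN/A, i.e. clearly beyond
#' the 70 pN/A classification threshold).
#'
#' @param n_beads number of bead residues (default 10).
#' @param region residue indices stiffened in state B (default 4:7).
#' @param base_stiffness_pn state-A tether stiffness, pN/A (default 150).
#' @param delta_target_pn engineered slope shift, pN/A (default +150).
#' @param pull_spring_pn pulling-spring constant used in the prediction
#'   (default the 7 kcal/mol/A^2 protocol spring).
#' @param seed RNG seed (generation is deterministic; kept for the fixture
#'   contract).
#' @return list with `structure_a`, `structure_b`, `backend_a`, `backend_b`
#'   and `ground_truth` (stabilized region, per-bead expected slopes and
#'   deltas).
#' @export
make_two_state_pair <- function(n_beads = 10, region = 4:7,
                                base_stiffness_pn = 150,
                                delta_target_pn = 150,
                                pull_spring_pn = convert_spring_constant(7),
                                seed = 1) {
  stopifnot(all(region %in% seq_len(n_beads)))
  set.seed(seed)
  xyz <- helix_curve(n_beads)
  slope_a <- series_slope(base_stiffness_pn, pull_spring_pn)
  slope_b <- slope_a + delta_target_pn
  if (slope_b >= pull_spring_pn) {
    stop("delta target unreachable: series slope cannot exceed the pull spring")
  }
  k_b_region <- slope_b * pull_spring_pn / (pull_spring_pn - slope_b)
  k_a <- rep(base_stiffness_pn, n_beads)
  k_b <- k_a
  k_b[region] <- k_b_region
  s <- mol_structure(bead_atoms(xyz))
  list(structure_a = s, structure_b = s,
       backend_a = build_harmonic_toy_backend(k_a, xyz),
       backend_b = build_harmonic_toy_backend(k_b, xyz),
       ground_truth = list(
         stabilized_region = region,
         tether_a_pn = k_a, tether_b_pn = k_b,
         expected_slope_a_pn = series_slope(k_a, pull_spring_pn),
         expected_slope_b_pn = series_slope(k_b, pull_spring_pn),
         expected_delta_pn = series_slope(k_b, pull_spring_pn) -
           series_slope(k_a, pull_spring_pn)))
}
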