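# Deterministic unit-sphere point set (generalized golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

vdw_radius <- function(element, atom_label = element) {
  r <- .vdw_radii[toupper(element)]
  if (anyNA(r)) {
    bad <- unique(atom_label[is.na(r)])
    stop("no van der Waals radius for atom(s): ", paste(bad, collapse = ", "))
  }
  unname(r)
}

#' Per-residue solvent-accessible surface area
#'
#' Shrake-Rupley numerical SASA: a deterministic spiral lattice of
#' `n_sphere_points` test points is placed on each heavy atom's solvent
#' sphere (vdW radius + probe radius, Bondi radii) and points falling inside
#' any neighbouring atom's solvent sphere are discarded.  Atom areas are
#' summed per residue.  Hydrogens are excluded so that selection does not
#' depend on whether a structure was protonated.
#'
#' @param structure a [mol_structure()].
#' @param probe_radius probe sphere radius in A (water: 1.4).
#' @param n_sphere_points test points per atom; 960 gives isolated-sphere
#'   areas exact and overlapping geometries well under 1% error.
#' @return named numeric vector of areas in A^2, names = residue indices.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_sphere_points = 960) {
  stopifnot(probe_radius > 0, n_sphere_points >= 12)
  a <- structure$atoms
  heavy <- toupper(a$element) != "H"
  a <- a[heavy, ]
  if (nrow(a) == 0) stop("structure has no heavy atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- vdw_radius(a$element, paste0(a$atom_name, "/", a$residue_index)) + probe_radius
  n <- nrow(a)
  pts <- sphere_points(n_sphere_points)
  area <- numeric(n)
  # neighbour lists from the pairwise distance matrix; fixture-scale systems
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    p <- pts * rad[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(exposed)) break
      dx <- p[exposed, 1] - xyz[j, 1]
      dy <- p[exposed, 2] - xyz[j, 2]
      dz <- p[exposed, 3] - xyz[j, 3]
      exposed[exposed] <- dx * dx + dy * dy + dz * dz >= rad[j]^2
    }
    area[i] <- sum(exposed) / n_sphere_points * 4 * pi * rad[i]^2
  }
  res <- tapply(area, a$residue_index, sum)
  out <- as.numeric(res)
  names(out) <- names(res)
  out[order(as.integer(names(out)))]
}

#' Select surface-exposed residues by SASA threshold
#'
#' Residues whose solvent-accessible surface area strictly exceeds the
#' threshold (default 30 A^2) are the pulling targets of a surface scan.
#'
#' @param sasa named numeric vector from [compute_sasa()].
#' @param threshold area cutoff in A^2.
#' @return an object of class `surface_set` with fields `sasa`, `threshold`,
#'   `selected` (ordered residue indices).
#' @export
select_surface_residues <- function(sasa, threshold = 30) {
  if (length(sasa) == 0) stop("empty SASA map")
  stopifnot(threshold >= 0, all(sasa >= 0))
  idx <- as.integer(names(sasa))
  if (anyNA(idx)) stop("SASA map must be named by residue index")
  sel <- sort(idx[sasa > threshold])
  structure(list(sasa = sasa, threshold = threshold, selected = sel),
            class = "surface_set")
}

#' @export
print.surface_set <- function(x, ...) {
  cat(sprintf("<surface_set> %d/%d residues with SASA > %g A^2\n",
              length(x$selected), length(x$sasa), x$threshold))
  invisible(x)
}

#' Outward pulling direction for a surface residue
#'
#' The pull direction is the unit vector from the centre of mass of the
#' atoms within `neighborhood_radius` of the SMD atom (the probed CA,
#' included in the set) to the SMD atom itself.  For a surface atom the
#' local centre of mass lies toward the protein interior, so the vector
#' approximates the outward local surface normal.
#'
#' @param structure a [mol_structure()].
#' @param smd_atom_id atom id of the probed CA.
#' @param neighborhood_radius neighbourhood radius in A (default 4).
#' @return unit 3-vector.
#' @export
pulling_direction <- function(structure, smd_atom_id, neighborhood_radius = 4) {
  xyz <- coords(structure)
  i <- atom_row(structure, smd_atom_id)
  p0 <- xyz[i, ]
  d <- sqrt(colSums((t(xyz) - p0)^2))
  nb <- which(d <= neighborhood_radius)
  if (length(nb) < 2) {
    stop("no atoms within ", neighborhood_radius, " A of SMD atom ", smd_atom_id)
  }
  m <- element_masses(structure)[nb]
  com <- colSums(xyz[nb, , drop = FALSE] * m) / sum(m)
  v <- p0 - com
  nv <- sqrt(sum(v^2))
  if (nv < 1e-6) {
    stop("degenerate pulling direction: neighbourhood centre of mass ",
         "coincides with SMD atom ", smd_atom_id)
  }
  v / nv
}

#' Partition atoms into the mobile zone and the fixed-CA shell
#'
#' All atoms within `free_radius` of the SMD atom (inclusive) are free to
#' move; CA atoms outside that zone are held fixed; non-CA atoms outside the
#' zone are unrestrained.
#'
#' @param structure a [mol_structure()].
#' @param smd_atom_id atom id of the probed CA.
#' @param free_radius zone radius in A (default 13).
#' @return list with `free_atom_ids` and `fixed_ca_ids`.
#' @export
partition_mobile_region <- function(structure, smd_atom_id, free_radius = 13) {
  stopifnot(free_radius > 0)
  xyz <- coords(structure)
  i <- atom_row(structure, smd_atom_id)
  d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
  free <- structure$atoms$atom_id[d <= free_radius]
  fixed <- structure$atoms$atom_id[d > free_radius & structure$atoms$atom_name == "CA"]
  list(free_atom_ids = free, fixed_ca_ids = fixed)
}

#' Full mechanical specification of one residue pull
#'
#' Collects the SMD atom, outward direction, mobile/fixed partition and the
#' mechanical protocol constants into a `pull_spec`.
#'
#' @param structure a [mol_structure()].
#' @param residue_index residue whose CA is pulled.
#' @param spring_constant virtual-spring constant, kcal/mol/A^2 (default 7).
#' @param pull_velocity dummy-atom speed, A/ps (default 0.15).
#' @param max_dummy_displacement pull length, A (default 2.5).
#' @param temperature bath temperature, K (default 310).
#' @param neighborhood_radius radius for [pulling_direction()].
#' @param free_radius radius for [partition_mobile_region()].
#' @param direction optional explicit unit pull direction (overrides the
#'   geometric construction; used by single-bead toys with no neighbours).
#' @return an object of class `pull_spec`.
#' @export
build_pull_spec <- function(structure, residue_index,
                            spring_constant = 7, pull_velocity = 0.15,
                            max_dummy_displacement = 2.5, temperature = 310,
                            neighborhood_radius = 4, free_radius = 13,
                            direction = NULL) {
  stopifnot(spring_constant > 0, pull_velocity > 0, max_dummy_displacement > 0,
            temperature >= 0)
  smd_atom_id <- structure$atoms$atom_id[ca_row(structure, residue_index)]
  if (is.null(direction)) {
    direction <- pulling_direction(structure, smd_atom_id, neighborhood_radius)
  }
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9) {
    stop("pull direction must be a unit vector")
  }
  part <- partition_mobile_region(structure, smd_atom_id, free_radius)
  if (!smd_atom_id %in% part$free_atom_ids) {
    stop("SMD atom not in its own free zone")   # cannot happen for radius > 0
  }
  structure(list(
    residue_index = residue_index,
    smd_atom_id = smd_atom_id,
    direction = direction,
    free_atom_ids = part$free_atom_ids,
    fixed_ca_ids = part$fixed_ca_ids,
    spring_constant = spring_constant,
    spring_constant_pn = convert_spring_constant(spring_constant),
    pull_velocity = pull_velocity,
    max_dummy_displacement = max_dummy_displacement,
    temperature = temperature
  ), class = "pull_spec")
}

#' @export
print.pull_spec <- function(x, ...) {
  cat(sprintf(paste0("<pull_spec> residue %d (atom %d), k = %.3g kcal/mol/A^2",
                     " (%.1f pN/A), v = %g A/ps, max d = %g A, %d free / %d fixed\n"),
              x$residue_index, x$smd_atom_id, x$spring_constant,
              x$spring_constant_pn, x$pull_velocity, x$max_dummy_displacement,
              length(x$free_atom_ids), length(x$fixed_ca_ids)))
  invisible(x)
}

#' Export SASA selection as TSV text
#'
#' @param structure a [mol_structure()].
#' @param surface_set a `surface_set` from [select_surface_residues()].
#' @return character scalar of TSV text with columns residue_index,
#'   residue_name, sasa_A2, selected.
#' @export
surface_set_tsv <- function(structure, surface_set) {
  a <- structure$atoms[!duplicated(structure$atoms$residue_index), ]
  idx <- as.integer(names(surface_set$sasa))
  df <- data.frame(
    residue_index = idx,
    residue_name = a$residue_name[match(idx, a$residue_index)],
    sasa_A2 = round(unname(surface_set$sasa), 3),
    selected = idx %in% surface_set$selected
  )
  paste(c(paste(names(df), collapse = "\t"),
          apply(df, 1, function(r) paste(trimws(r), collapse = "\t")), ""),
        collapse = "\n")
}
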