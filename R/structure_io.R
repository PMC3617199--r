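#' Molecular structures
#'
#' A `mol_structure` holds one model of a protein (or toy bead system) as a
#' flat atom table: columns `atom_id`, `atom_name`, `element`,
#' `residue_index`, `residue_name`, `chain_id`, `x`, `y`, `z`, `occupancy`,
#' `bfactor`.  Every standard amino-acid residue carries exactly one `CA`
#' atom; `atom_id`s are unique; coordinates are finite.
#'
#' @param atoms data.frame with the columns listed above.
#' @return an object of class `mol_structure`.
#' @export
mol_structure <- function(atoms) {
  required <- c("atom_id", "atom_name", "element", "residue_index",
                "residue_name", "chain_id", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$bfactor)) atoms$bfactor <- 0
  rownames(atoms) <- NULL
  s <- structure(list(atoms = atoms), class = "mol_structure")
  validate_structure(s)
  s
}

#' @export
print.mol_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<mol_structure> %d atoms, %d residues, chains: %s\n",
              nrow(a), length(unique(a$residue_index)),
              paste(unique(a$chain_id), collapse = ",")))
  invisible(x)
}

validate_structure <- function(s) {
  a <- s$atoms
  if (nrow(a) == 0) stop("structure contains no atoms")
  if (anyDuplicated(a$atom_id)) {
    dup <- a$atom_id[duplicated(a$atom_id)][1]
    stop("duplicate atom serial number: ", dup)
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in structure")
  std <- a[a$residue_name %in% .standard_residues, ]
  if (nrow(std) > 0) {
    n_ca <- tapply(std$atom_name == "CA", paste(std$chain_id, std$residue_index), sum)
    if (any(n_ca != 1)) {
      bad <- names(n_ca)[n_ca != 1][1]
      stop("standard residue without exactly one CA atom: ", bad)
    }
  }
  for (ch in unique(a$chain_id)) {
    ri <- a$residue_index[a$chain_id == ch]
    ri <- ri[!duplicated(ri)]
    if (is.unsorted(ri, strictly = TRUE)) {
      stop("residue indices not strictly increasing within chain ", ch)
    }
  }
  invisible(s)
}

#' @rdname mol_structure
#' @param s a `mol_structure`.
#' @export
coords <- function(s) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

set_coords <- function(s, xyz) {
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}

#' @rdname mol_structure
#' @export
residue_indices <- function(s) unique(s$atoms$residue_index)

# Row index of the CA atom of a residue (first chain hit).
ca_row <- function(s, residue_index) {
  i <- which(s$atoms$residue_index == residue_index & s$atoms$atom_name == "CA")
  if (length(i) == 0) stop("residue ", residue_index, " has no CA atom")
  i[1]
}

ca_rows <- function(s) which(s$atoms$atom_name == "CA")

atom_row <- function(s, atom_id) {
  i <- match(atom_id, s$atoms$atom_id)
  if (is.na(i)) stop("no atom with id ", atom_id)
  i
}

element_masses <- function(s) {
  el <- toupper(s$atoms$element)
  m <- .atomic_masses[el]
  if (anyNA(m)) {
    stop("no atomic mass for element(s): ",
         paste(unique(el[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

guess_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "SE", "MG", "ZN", "FE"), two, one)
}

#' Read a protein structure from PDB text
#'
#' Parses `ATOM`/`HETATM` records with fixed-width columns.  Multi-model
#' (NMR-style) files are handled through `model_index`; alternate locations
#' are resolved to the highest-occupancy conformer (ties keep the first
#' encountered).  Hydrogens are retained if present.  Non-protein records
#' (waters, ions, ligands) are dropped by default.
#'
#' @param pdb_text character scalar (or vector of lines) of PDB text.
#' @param model_index 1-based model to extract; files without MODEL records
#'   count as a single model.
#' @param keep_hetatm keep HETATM records (waters/ions) instead of stripping
#'   them.
#' @return a [mol_structure()].
#' @export
read_structure <- function(pdb_text, model_index = 1, keep_hetatm = FALSE) {
  lines <- if (length(pdb_text) == 1) strsplit(pdb_text, "\n", fixed = TRUE)[[1]] else pdb_text
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  n_models <- max(1L, length(model_starts))
  if (model_index < 1 || model_index > n_models) {
    stop("model_index ", model_index, " out of range: file has ", n_models, " model(s)")
  }
  if (length(model_starts) > 0) {
    ends <- which(trimws(rec) == "ENDMDL")
    start <- model_starts[model_index]
    end <- ends[ends > start]
    end <- if (length(end) > 0) end[1] else length(lines)
    keep_range <- seq(start, end)
  } else {
    keep_range <- seq_along(lines)
  }
  sel <- keep_range[trimws(rec[keep_range]) %in%
                      (if (keep_hetatm) c("ATOM", "HETATM") else "ATOM")]
  if (length(sel) == 0) stop("no ATOM records in requested model")

  fw <- function(l, a, b) substr(l, a, b)
  l <- lines[sel]
  num <- function(str, what) {
    v <- suppressWarnings(as.numeric(str))
    bad <- which(!is.finite(v) & trimws(str) != "")
    bad2 <- which(trimws(str) == "")
    bad <- c(bad, if (what %in% c("x", "y", "z", "serial")) bad2)
    if (length(bad) > 0) {
      stop("malformed ATOM record (bad ", what, ") at line ", sel[min(bad)],
           ": ", l[min(bad)])
    }
    v
  }
  atoms <- data.frame(
    atom_id = as.integer(num(fw(l, 7, 11), "serial")),
    atom_name = trimws(fw(l, 13, 16)),
    altloc = fw(l, 17, 17),
    residue_name = trimws(fw(l, 18, 20)),
    chain_id = trimws(fw(l, 22, 22)),
    residue_index = as.integer(num(fw(l, 23, 26), "residue number")),
    x = num(fw(l, 31, 38), "x"),
    y = num(fw(l, 39, 46), "y"),
    z = num(fw(l, 47, 54), "z"),
    occupancy = num(fw(l, 55, 60), "occupancy"),
    bfactor = num(fw(l, 61, 66), "bfactor"),
    element = trimws(fw(l, 77, 78)),
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$bfactor[is.na(atoms$bfactor)] <- 0
  noel <- atoms$element == ""
  atoms$element[noel] <- guess_element(atoms$atom_name[noel])
  atoms$chain_id[atoms$chain_id == ""] <- "A"

  # altloc resolution: highest occupancy per (chain, residue, atom name),
  # ties keep the first record encountered
  has_alt <- atoms$altloc != " " & atoms$altloc != ""
  if (any(has_alt)) {
    key <- paste(atoms$chain_id, atoms$residue_index, atoms$atom_name)
    ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
    atoms <- atoms[ord, ]
    atoms <- atoms[!duplicated(paste(atoms$chain_id, atoms$residue_index, atoms$atom_name)), ]
    atoms <- atoms[order(atoms$atom_id), ]
  }
  atoms$altloc <- NULL
  mol_structure(atoms)
}

#' Replace a residue's side chain by alanine
#'
#' Side-chain atoms beyond the beta carbon are removed, the residue is
#' renamed `ALA`, and a CB atom is built from ideal tetrahedral geometry
#' (1.53 A bond from CA) when the original residue lacks one.  Backbone
#' coordinates are untouched.  Glycine cannot be mutated (no CB template).
#'
#' @param structure a [mol_structure()].
#' @param residue_index residue to mutate (standard amino acid with backbone
#'   atoms N, CA, C, O present).
#' @return the mutated `mol_structure`.
#' @export
mutate_to_alanine <- function(structure, residue_index) {
  a <- structure$atoms
  in_res <- a$residue_index == residue_index
  if (!any(in_res)) stop("no residue with index ", residue_index)
  res_name <- a$residue_name[in_res][1]
  if (!res_name %in% .standard_residues) {
    stop("residue ", residue_index, " (", res_name, ") is not a standard amino acid")
  }
  if (res_name == "GLY") {
    stop("unsupported mutation: glycine (", residue_index, ") has no CB template")
  }
  if (res_name == "ALA") return(structure)
  for (nm in c("N", "CA", "C", "O")) {
    if (!nm %in% a$atom_name[in_res]) {
      stop("residue ", residue_index, " lacks backbone atom ", nm)
    }
  }
  keep_names <- c(.backbone_atom_names, "CB")
  drop <- in_res & !(a$atom_name %in% keep_names)
  a <- a[!drop, ]
  in_res <- a$residue_index == residue_index
  a$residue_name[in_res] <- "ALA"
  if (!"CB" %in% a$atom_name[in_res]) {
    pos <- function(nm) {
      r <- which(in_res & a$atom_name == nm)
      as.numeric(a[r, c("x", "y", "z")])
    }
    cb <- ideal_cb(pos("N"), pos("CA"), pos("C"))
    ca_idx <- which(in_res & a$atom_name == "CA")
    new_row <- a[ca_idx, ]
    new_row$atom_name <- "CB"
    new_row$element <- "C"
    new_row$atom_id <- max(a$atom_id) + 1L
    new_row[, c("x", "y", "z")] <- as.list(cb)
    # insert after CA to keep a conventional atom order within the residue
    tail_rows <- if (ca_idx < nrow(a)) a[(ca_idx + 1):nrow(a), , drop = FALSE] else a[0, ]
    a <- rbind(a[seq_len(ca_idx), ], new_row, tail_rows)
  }
  mol_structure(a)
}

# Ideal tetrahedral CB from backbone N/CA/C positions; 1.53 A CA-CB bond,
# 110.5 deg N-CA-CB and C-CA-CB angles, L-amino-acid chirality.
ideal_cb <- function(n, ca, c, bond = 1.53, theta_deg = 110.5) {
  u1 <- n - ca; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c - ca; u2 <- u2 / sqrt(sum(u2^2))
  bis <- u1 + u2; bis <- bis / sqrt(sum(bis^2))
  nrm <- c(u1[2] * u2[3] - u1[3] * u2[2],
           u1[3] * u2[1] - u1[1] * u2[3],
           u1[1] * u2[2] - u1[2] * u2[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  cos_t <- cos(theta_deg * pi / 180)
  cos_a <- -cos_t / sum(bis * u1)
  cos_a <- min(1, max(-1, cos_a))
  sin_a <- sqrt(1 - cos_a^2)
  ca + bond * (-cos_a * bis + sin_a * nrm)
}

format_pdb_atoms <- function(atoms) {
  name_fmt <- ifelse(nchar(atoms$atom_name) <= 3,
                     sprintf(" %-3s", atoms$atom_name),
                     sprintf("%-4s", atoms$atom_name))
  sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$atom_id, name_fmt, atoms$residue_name,
          substr(atoms$chain_id, 1, 1), atoms$residue_index,
          atoms$x, atoms$y, atoms$z, atoms$occupancy, atoms$bfactor,
          toupper(atoms$element))
}

#' Write a structure as PDB text
#'
#' @param structure a [mol_structure()].
#' @return character scalar of PDB text.
#' @export
write_structure <- function(structure) {
  a <- structure$atoms
  if (any(a$bfactor > 999.99 | a$bfactor < -99.99)) {
    stop("B-factor value not representable in %6.2f column")
  }
  paste(c(format_pdb_atoms(a), "TER", "END", ""), collapse = "\n")
}

#' Export a per-residue scalar through the B-factor column
#'
#' Writes the structure as PDB text with every atom's B-factor set to its
#' residue's value (0.00 where no value is supplied), so external viewers
#' can color surfaces by, e.g., resistance coefficients.
#'
#' @param structure a [mol_structure()].
#' @param per_residue_value named numeric vector, names = residue indices.
#' @return character scalar of PDB text.
#' @export
write_colored_structure <- function(structure, per_residue_value) {
  stopifnot(is.numeric(per_residue_value))
  if (length(per_residue_value) > 0 && !all(is.finite(per_residue_value))) {
    stop("per-residue values must be finite")
  }
  if (any(per_residue_value > 999.99 | per_residue_value < -99.99)) {
    stop("value not representable in B-factor column (%6.2f): magnitude too large")
  }
  v <- per_residue_value[as.character(structure$atoms$residue_index)]
  v[is.na(v)] <- 0
  structure$atoms$bfactor <- as.numeric(v)
  write_structure(structure)
}

#' Extract per-residue values back from a colored PDB
#'
#' Inverse of [write_colored_structure()]: returns the B-factor of each
#' residue's first atom, named by residue index.
#'
#' @param structure a [mol_structure()] read back from colored PDB text.
#' @return named numeric vector.
#' @export
read_residue_values <- function(structure) {
  a <- structure$atoms
  first <- !duplicated(a$residue_index)
  stats::setNames(a$bfactor[first], a$residue_index[first])
}

#' Write a multi-model PDB trajectory
#'
#' @param structure a [mol_structure()] providing the atom table.
#' @param frames list of n_atoms x 3 coordinate matrices.
#' @return character scalar of multi-model PDB text.
#' @export
write_trajectory <- function(structure, frames) {
  blocks <- vapply(seq_along(frames), function(i) {
    s <- set_coords(structure, frames[[i]])
    paste(c(sprintf("MODEL     %4d", i), format_pdb_atoms(s$atoms), "ENDMDL"),
          collapse = "\n")
  }, character(1))
  paste(c(blocks, "END", ""), collapse = "\n")
}
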