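# In-code fixtures and independent oracles shared across the suite.

pdb_atom_line <- function(serial, name, resname, resseq, x, y, z,
                          occ = 1, bf = 0, element = substr(name, 1, 1),
                          altloc = " ", chain = "A") {
  name_f <- if (nchar(name) <= 3) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_f, altloc, resname, chain, resseq, x, y, z, occ, bf,
          element)
}

# three glycine-like residues on a line, CA only plus N to exercise naming
three_residue_pdb <- function() {
  paste(c(
    pdb_atom_line(1, "N",  "GLY", 1, 0, 0, 0, element = "N"),
    pdb_atom_line(2, "CA", "GLY", 1, 1.5, 0, 0),
    pdb_atom_line(3, "N",  "GLY", 2, 0, 3.8, 0, element = "N"),
    pdb_atom_line(4, "CA", "GLY", 2, 1.5, 3.8, 0),
    pdb_atom_line(5, "N",  "GLY", 3, 0, 7.6, 0, element = "N"),
    pdb_atom_line(6, "CA", "GLY", 3, 1.5, 7.6, 0),
    "TER", "END"), collapse = "\n")
}

two_model_pdb <- function() {
  paste(c(
    "MODEL        1",
    pdb_atom_line(1, "CA", "GLY", 1, 0, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "CA", "GLY", 1, 9, 9, 9),
    "ENDMDL",
    "END"), collapse = "\n")
}

# brute-force centre of mass
com_oracle <- function(xyz, masses) {
  colSums(xyz * masses) / sum(masses)
}

# closed-form OLS slope by the normal equations
ols_slope_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# definitional Pearson correlation
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# pooled-variance two-sample t by the textbook formula
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

# Monte-Carlo SASA oracle for a set of spheres: sample points uniformly on
# each solvent sphere, count those outside all other spheres
mc_sasa_oracle <- function(xyz, radii, probe = 1.4, n_mc = 1e6, seed = 99) {
  set.seed(seed)
  r <- radii + probe
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    u <- matrix(rnorm(3 * n_mc), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * r[i], 2, xyz[i, ], "+")
    outside <- rep(TRUE, n_mc)
    for (j in setdiff(seq_len(nrow(xyz)), i)) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      outside <- outside & d2 >= r[j]^2
    }
    total <- total + mean(outside) * 4 * pi * r[i]^2
  }
  total
}

# union-find connected components over an adjacency rule
union_find_patches_oracle <- function(idx, xyz, values, threshold, cutoff,
                                      min_size = 2) {
  keep <- values >= threshold
  idx <- idx[keep]; xyz <- xyz[keep, , drop = FALSE]
  n <- length(idx)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) {
      parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(idx, roots)
  comps <- Filter(function(cc) length(cc) >= min_size, comps)
  lapply(unname(comps), sort)
}

make_random_cluster <- function(n, seed, spread = 6) {
  set.seed(seed)
  xyz <- matrix(rnorm(3 * n, sd = spread), ncol = 3)
  mol_structure(data.frame(
    atom_id = seq_len(n), atom_name = "CA", element = "C",
    residue_index = seq_len(n), residue_name = "BEA", chain_id = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1, bfactor = 0))
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}
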