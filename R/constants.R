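# Internal unit system: length in Angstrom, time in ps, mass in amu (g/mol),
# energy in kcal/mol.  Forces are reported to users in pN.

# 1 kcal/mol/A expressed in pN: 4184 J / N_A / 1e-10 m, in units of 1e-12 N.
.pn_per_kcal_mol_ang <- 4184 / 6.02214076e23 / 1e-10 * 1e12

# 1 kcal/mol in the "natural" dynamics unit amu*A^2/ps^2 (1 amu*A^2/ps^2 = 10 J/mol).
.kcal_to_akma <- 418.4

# Boltzmann constant, kcal/mol/K.
.kB <- 8.314462618 / 4184

.backbone_atom_names <- c("N", "CA", "C", "O", "OXT", "H", "HN", "H1", "H2", "H3", "HA")

.standard_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# Bondi van der Waals radii (A) for the elements that occur in protein heavy
# atoms plus a few common hetero elements.
.vdw_radii <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, CA = 2.31,
  MG = 1.73, ZN = 1.39, "NA" = 2.27, K = 2.75, FE = 1.94
)

.atomic_masses <- c(
  C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974, H = 1.008,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, SE = 78.971,
  CA = 40.078, MG = 24.305, ZN = 65.38, "NA" = 22.99, K = 39.098, FE = 55.845
)

#' Convert a spring constant from kcal/mol/A^2 to pN/A
#'
#' Pulling-protocol spring constants are conventionally quoted in
#' kcal/mol/A^2 while resistance coefficients are reported in pN/A.  The
#' conversion factor is 1 kcal/mol/A = 69.4769 pN (from 1 kcal = 4184 J and
#' Avogadro's number), so the same factor converts kcal/mol/A^2 to pN/A.
#'
#' @param k spring constant in kcal/mol/A^2 (non-negative).
#' @return the spring constant in pN/A.
#' @examples
#' convert_spring_constant(7) # the default pulling spring, ~486.3 pN/A
#' @export
convert_spring_constant <- function(k) {
  stopifnot(is.numeric(k), all(k >= 0))
  k * .pn_per_kcal_mol_ang
}
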