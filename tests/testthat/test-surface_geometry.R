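single_atom_structure <- function(x = 0, y = 0, z = 0, id = 1, res = 1) {
  data.frame(atom_id = id, atom_name = "CA", element = "C",
             residue_index = res, residue_name = "BEA", chain_id = "A",
             x = x, y = y, z = z, occupancy = 1, bfactor = 0)
}

test_that("SASA matches closed forms and a Monte-Carlo oracle", {
  # isolated carbon: full solvent sphere 4*pi*(1.70+1.4)^2
  s1 <- mol_structure(single_atom_structure())
  expect_equal(unname(compute_sasa(s1)), 4 * pi * 3.10^2, tolerance = 5e-3)

  # two atoms far apart: no occlusion
  s2 <- mol_structure(rbind(single_atom_structure(),
                            single_atom_structure(x = 100, id = 2, res = 2)))
  sasa2 <- compute_sasa(s2)
  expect_equal(unname(sasa2), rep(4 * pi * 3.10^2, 2), tolerance = 5e-3)

  # overlapping pair vs brute-force Monte-Carlo surface integration
  xyz <- rbind(c(0, 0, 0), c(2.2, 0, 0))
  s3 <- mol_structure(rbind(single_atom_structure(),
                            single_atom_structure(x = 2.2, id = 2, res = 2)))
  mc <- mc_sasa_oracle(xyz, radii = c(1.70, 1.70), n_mc = 1e6)
  expect_equal(sum(compute_sasa(s3)), mc, tolerance = 0.02)

  a <- single_atom_structure(); a$element <- "XX"
  expect_error(compute_sasa(mol_structure(a)), "van der Waals")
})

test_that("SASA is rigid-motion invariant and sums over residues", {
  fx <- make_fixture("ideal_helix_peptide", n_residues = 6)
  base <- compute_sasa(fx$structure)
  rot <- random_rotation(7)
  moved <- fx$structure
  xyz <- coords(fx$structure) %*% t(rot)
  moved$atoms$x <- xyz[, 1] + 11.3
  moved$atoms$y <- xyz[, 2] - 4.2
  moved$atoms$z <- xyz[, 3] + 0.7
  expect_equal(compute_sasa(moved), base, tolerance = 5e-3)

  # per-residue areas partition the whole-structure area
  merged <- fx$structure
  merged$atoms$residue_index <- 1L
  merged$atoms$residue_name <- "BEA"
  expect_equal(sum(base), unname(compute_sasa(merged)), tolerance = 1e-9)
})

test_that("surface selection is strict and ordered; buried residues drop out", {
  sel <- select_surface_residues(c("1" = 29.9, "2" = 30.0, "3" = 30.1), 30)
  expect_equal(sel$selected, 3L)
  expect_error(select_surface_residues(numeric(0)), "empty")

  cage <- make_fixture("atom_cage")
  sasa <- compute_sasa(cage$structure)
  buried <- cage$ground_truth$buried_residue
  expect_equal(unname(sasa[as.character(buried)]), 0)
  expect_false(buried %in% select_surface_residues(sasa, 30)$selected)
})

test_that("pulling direction points outward and matches the COM oracle", {
  shell <- make_fixture("hemispherical_shell")
  apex_id <- shell$structure$atoms$atom_id[
    shell$structure$atoms$residue_index == shell$ground_truth$apex_residue]
  d <- pulling_direction(shell$structure, apex_id)
  expect_equal(d, c(0, 0, 1), tolerance = 1e-6)

  # single neighbour straight below
  s <- mol_structure(rbind(single_atom_structure(z = 0),
                           single_atom_structure(z = -2, id = 2, res = 2)))
  expect_equal(pulling_direction(s, 1), c(0, 0, 1), tolerance = 1e-12)

  # random cluster vs direct mass-weighted summation
  cl <- make_random_cluster(20, seed = 3, spread = 1.5)
  xyz <- coords(cl)
  i <- 5
  nb <- which(sqrt(colSums((t(xyz) - xyz[i, ])^2)) <= 4)
  com <- com_oracle(xyz[nb, , drop = FALSE], rep(12.011, length(nb)))
  v <- xyz[i, ] - com
  expect_equal(pulling_direction(cl, i), v / sqrt(sum(v^2)), tolerance = 1e-12)

  cage <- make_fixture("atom_cage")
  centre_id <- cage$structure$atoms$atom_id[
    cage$structure$atoms$residue_index == cage$ground_truth$buried_residue]
  expect_error(pulling_direction(cage$structure, centre_id), "degenerate")
})

test_that("pulling direction is translation-invariant and rotation-equivariant", {
  cl <- make_random_cluster(15, seed = 11, spread = 1.5)
  d0 <- pulling_direction(cl, 4)
  shifted <- cl
  shifted$atoms$x <- shifted$atoms$x + 5
  shifted$atoms$y <- shifted$atoms$y - 2
  expect_equal(pulling_direction(shifted, 4), d0, tolerance = 1e-12)
  rot <- random_rotation(5)
  rotated <- cl
  xyz <- coords(cl) %*% t(rot)
  rotated$atoms$x <- xyz[, 1]; rotated$atoms$y <- xyz[, 2]; rotated$atoms$z <- xyz[, 3]
  expect_equal(pulling_direction(rotated, 4), as.numeric(rot %*% d0),
               tolerance = 1e-12)
})

test_that("mobile/fixed partition follows the inclusive 13 A rule", {
  # beads at 0, 13 and 20 A: 13 A is inside the free zone (<= convention)
  s <- mol_structure(rbind(
    single_atom_structure(),
    single_atom_structure(x = 13, id = 2, res = 2),
    single_atom_structure(x = 20, id = 3, res = 3)))
  part <- partition_mobile_region(s, 1, free_radius = 13)
  expect_setequal(part$free_atom_ids, c(1, 2))
  expect_equal(part$fixed_ca_ids, 3)
  expect_length(intersect(part$free_atom_ids, part$fixed_ca_ids), 0)

  # non-CA atoms outside the zone belong to neither set
  fx <- make_fixture("ideal_helix_peptide", n_residues = 30)
  smd_id <- fx$structure$atoms$atom_id[
    fx$structure$atoms$residue_index == 1 & fx$structure$atoms$atom_name == "CA"]
  p2 <- partition_mobile_region(fx$structure, smd_id)
  far_side_chain <- fx$structure$atoms$atom_id[
    fx$structure$atoms$residue_index == 30 & fx$structure$atoms$atom_name == "CB"]
  expect_false(far_side_chain %in% p2$free_atom_ids)
  expect_false(far_side_chain %in% p2$fixed_ca_ids)
  far_ca <- fx$structure$atoms$atom_id[
    fx$structure$atoms$residue_index == 30 & fx$structure$atoms$atom_name == "CA"]
  expect_true(far_ca %in% p2$fixed_ca_ids)

  # radius beyond the structure diameter leaves nothing fixed
  p3 <- partition_mobile_region(fx$structure, smd_id, free_radius = 1000)
  expect_length(p3$fixed_ca_ids, 0)
})

test_that("spring-constant conversion follows from unit algebra", {
  expect_equal(convert_spring_constant(0), 0)
  expect_equal(convert_spring_constant(1), 69.4786, tolerance = 1e-3)
  expect_equal(convert_spring_constant(7), 486.35, tolerance = 1e-3)
  # independent derivation: kcal -> J -> N at one angstrom, per molecule
  pn <- 4184 / 6.02214076e23 / 1e-10 * 1e12
  expect_equal(convert_spring_constant(1), pn, tolerance = 1e-12)
})
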