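cold_pull <- function(fx, velocity = 0.15, seed = 1, backend = fx$backend,
                      k = 7) {
  ps <- build_pull_spec(fx$structure, 1, temperature = 0,
                        direction = c(0, 0, 1), pull_velocity = velocity,
                        spring_constant = k)
  run_smd(fx$structure, ps, backend, seed = seed)
}

test_that("force-extension traces satisfy their invariants", {
  fx <- make_fixture("single_bead")
  tr <- cold_pull(fx)
  d <- tr$samples$displacement
  expect_true(all(d >= 0))
  expect_true(all(diff(d) > 0))
  expect_lte(max(d), 2.5 + 1e-9)
  expect_true(all(is.finite(tr$samples$force_pN)))
  expect_equal(d[1], 0)
  expect_equal(tr$samples$force_pN[1], 0)  # spring starts relaxed
})

test_that("pulled slope matches the series-spring equilibrium oracle", {
  fx <- make_fixture("single_bead")
  gt <- fx$ground_truth
  slope <- fit_resistance(cold_pull(fx))
  expect_equal(slope, gt$expected_slope_pn, tolerance = 0.05)

  # immobilized SMD atom: the dummy spring is the only compliance
  rigid <- fx$backend
  rigid$movable_mask[1] <- FALSE
  expect_equal(fit_resistance(cold_pull(fx, backend = rigid)),
               convert_spring_constant(7), tolerance = 0.01)

  # untethered bead: only friction drag, slope a few percent of k_p at most
  free <- make_fixture("single_bead", tether_stiffness_pn = 0)
  expect_lt(abs(fit_resistance(cold_pull(free))),
            0.05 * convert_spring_constant(7))
})

test_that("slower pulling converges monotonically to the analytic stiffness", {
  fx <- make_fixture("single_bead")
  gt <- fx$ground_truth$expected_slope_pn
  slopes <- vapply(c(0.6, 0.3, 0.15), function(v) {
    fit_resistance(cold_pull(fx, velocity = v))
  }, numeric(1))
  errs <- abs(slopes - gt)
  expect_true(all(diff(errs) < 0))
  expect_equal(slopes[3], gt, tolerance = 0.05)
})

test_that("replicates differ only by seed and warn below twelve", {
  fx <- make_fixture("single_bead")
  ps <- build_pull_spec(fx$structure, 1, direction = c(0, 0, 1))
  expect_warning(run_replicates(fx$structure, ps, fx$backend,
                                n_replicates = 3, seed_base = 5),
                 "12 replicates")
  tr <- suppressWarnings(
    run_replicates(fx$structure, ps, fx$backend, n_replicates = 2, seed_base = 5))
  expect_equal(vapply(tr, `[[`, numeric(1), "replicate_seed"), c(6, 7))
  again <- run_smd(fx$structure, ps, fx$backend, seed = 6)
  expect_identical(tr[[1]]$samples, again$samples)
  expect_false(identical(tr[[1]]$samples$force_pN, tr[[2]]$samples$force_pN))

  # low-noise toy: 12 replicate slopes have SEM below 5% of the mean
  tr12 <- run_replicates(fx$structure, ps, fx$backend, n_replicates = 12,
                         seed_base = 10)
  slopes <- vapply(tr12, fit_resistance, numeric(1))
  expect_lt(sd(slopes) / sqrt(12) / mean(slopes), 0.05)
})

test_that("fixed-shell CA atoms never move during a pull", {
  fx <- make_fixture("two_region_cluster")
  ps <- build_pull_spec(fx$structure, 3)
  expect_gt(length(ps$fixed_ca_ids), 0)
  tr <- run_smd(fx$structure, ps, fx$backend, seed = 2)
  rows <- match(ps$fixed_ca_ids, fx$structure$atoms$atom_id)
  expect_identical(tr$final_positions[rows, ], coords(fx$structure)[rows, ])
})

test_that("surface scans cover every selected residue and record failures", {
  fx <- make_fixture("bead_chain", n_beads = 5)
  sasa <- compute_sasa(fx$structure)
  surf <- select_surface_residues(sasa, 30)
  expect_setequal(surf$selected, 1:5)
  cfg <- list(n_replicates = 2, seed_base = 3)
  scan <- scan_surface(fx$structure, surf, cfg, fx$backend)
  expect_setequal(names(scan), as.character(1:5))
  expect_length(scan[["2"]], 2)

  # degenerate-direction residues are skipped but reported
  cage <- make_fixture("atom_cage")
  sasa_c <- compute_sasa(cage$structure)
  surf_c <- select_surface_residues(sasa_c, 30)
  surf_c$selected <- sort(unique(c(surf_c$selected,
                                   cage$ground_truth$buried_residue)))
  scan_c <- scan_surface(cage$structure, surf_c,
                         list(n_replicates = 1, seed_base = 1), cage$backend)
  fails <- attr(scan_c, "failures")
  expect_true(as.character(cage$ground_truth$buried_residue) %in% names(fails))
  expect_false(as.character(cage$ground_truth$buried_residue) %in% names(scan_c))
  expect_gt(length(scan_c), 0)
})

test_that("equilibration minimizes, honours schedules and stays near reference", {
  fx <- make_fixture("ideal_helix_peptide", n_residues = 6)
  # perturb away from the reference; T = 0 minimization must lower the energy
  pert <- fx$structure
  set.seed(8)
  xyz <- coords(pert) + matrix(rnorm(nrow(pert$atoms) * 3, sd = 0.3), ncol = 3)
  pert$atoms$x <- xyz[, 1]; pert$atoms$y <- xyz[, 2]; pert$atoms$z <- xyz[, 3]
  e_before <- fx$backend$evaluate(coords(pert))$energy
  eq <- equilibrate(pert, fx$backend, schedule = list(), minimize = TRUE)
  expect_lt(fx$backend$evaluate(coords(eq))$energy, e_before)

  # zero-duration stages leave the minimized structure untouched
  eq2 <- equilibrate(pert, fx$backend,
                     schedule = list(list(restrain = "none", duration_ps = 0)),
                     minimize = TRUE)
  expect_equal(coords(eq2), coords(eq))

  # tethered toy at 310 K: displacement consistent with equipartition
  bead <- make_fixture("single_bead", tether_stiffness_pn = 200)
  spec <- integrator_spec(seed = 31)
  eq3 <- equilibrate(bead$structure, bead$backend,
                     schedule = list(list(restrain = "none", duration_ps = 100)),
                     spec = spec, minimize = FALSE)
  disp2 <- sum(coords(eq3)^2)
  kT <- 8.314462618 / 4184 * 310
  k_kcal <- 200 / (4184 / 6.02214076e23 / 1e-10 * 1e12)
  # |x|^2 for one 3D draw: mean 3 kT/k, sd sqrt(6) kT/k -- allow 4 sd
  expect_lt(disp2, (3 + 4 * sqrt(6)) * kT / k_kcal)
})
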