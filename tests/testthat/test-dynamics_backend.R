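pn_per_kcal <- 4184 / 6.02214076e23 / 1e-10 * 1e12

test_that("elastic network obeys Hooke's law and forces are -grad E", {
  two <- mol_structure(rbind(
    data.frame(atom_id = 1, atom_name = "CA", element = "C", residue_index = 1,
               residue_name = "BEA", chain_id = "A", x = 0, y = 0, z = 0,
               occupancy = 1, bfactor = 0),
    data.frame(atom_id = 2, atom_name = "CA", element = "C", residue_index = 2,
               residue_name = "BEA", chain_id = "A", x = 3, y = 0, z = 0,
               occupancy = 1, bfactor = 0)))
  bk <- build_enm_backend(two, params = list(cutoff = 5, spring = 2))

  at_rest <- bk$evaluate(coords(two))
  expect_equal(at_rest$energy, 0)
  expect_equal(at_rest$forces, matrix(0, 2, 3))

  # stretch by delta: restoring force k*delta on each atom, energy k/2 delta^2
  delta <- 0.4
  x <- coords(two); x[2, 1] <- 3 + delta
  ev <- bk$evaluate(x)
  expect_equal(ev$energy, 0.5 * 2 * delta^2)
  expect_equal(ev$forces[2, 1], -2 * delta)
  expect_equal(ev$forces[1, 1], 2 * delta)

  # random cluster: central differences of E reproduce the forces
  cl <- make_random_cluster(15, seed = 21, spread = 2.5)
  bk2 <- build_enm_backend(cl, params = list(cutoff = 6, spring = 1.3))
  set.seed(4)
  x <- coords(cl) + matrix(rnorm(45, sd = 0.2), ncol = 3)
  f <- bk2$evaluate(x)$forces
  h <- 1e-5
  for (probe in list(c(2, 1), c(7, 3), c(14, 2))) {
    xp <- x; xp[probe[1], probe[2]] <- xp[probe[1], probe[2]] + h
    xm <- x; xm[probe[1], probe[2]] <- xm[probe[1], probe[2]] - h
    fd <- -(bk2$evaluate(xp)$energy - bk2$evaluate(xm)$energy) / (2 * h)
    expect_equal(f[probe[1], probe[2]], fd, tolerance = 1e-4)
  }
})

test_that("disconnected elastic networks are rejected with component sizes", {
  far <- mol_structure(rbind(
    data.frame(atom_id = 1:2, atom_name = "CA", element = "C",
               residue_index = 1:2, residue_name = "BEA", chain_id = "A",
               x = c(0, 3), y = 0, z = 0, occupancy = 1, bfactor = 0),
    data.frame(atom_id = 3, atom_name = "CA", element = "C", residue_index = 3,
               residue_name = "BEA", chain_id = "A", x = 50, y = 0, z = 0,
               occupancy = 1, bfactor = 0)))
  expect_error(build_enm_backend(far, params = list(cutoff = 5)),
               "disconnected.*component", perl = TRUE)
})

test_that("harmonic tethers give exact energies and forces", {
  ref <- matrix(0, 1, 3)
  bk <- build_harmonic_toy_backend(100, ref)   # 100 pN/A
  ev <- bk$evaluate(matrix(c(1, 0, 0), 1, 3))
  expect_equal(ev$forces[1, 1] * pn_per_kcal, -100)   # 100 pN toward the anchor
  d <- 0.7
  k_kcal <- 100 / pn_per_kcal
  expect_equal(bk$evaluate(matrix(c(0, d, 0), 1, 3))$energy, 0.5 * k_kcal * d^2)

  free <- build_harmonic_toy_backend(0, ref)
  expect_equal(free$evaluate(matrix(5, 1, 3))$forces, matrix(0, 1, 3))
})

test_that("T=0, zero-friction integration reduces to Verlet: period and drift", {
  fx <- make_fixture("single_bead")          # 486.34 pN/A tether, 100 amu
  k_kcal <- 7
  m <- 100
  omega <- sqrt(k_kcal * 418.4 / m)
  period <- 2 * pi / omega
  spec <- integrator_spec(timestep_fs = 2, friction_ps = 0, temperature_K = 0)
  x0 <- matrix(c(0.5, 0, 0), 1, 3)
  out <- resistmap:::langevin_run(fx$backend, x0, matrix(0, 1, 3), spec,
                                  n_steps = 25000, sample_every = 1,
                                  record_rows = 1L)
  x <- out$traj[, 1]
  crossings <- which(diff(sign(x)) < 0)
  measured <- diff(range(crossings)) * 0.002 / (length(crossings) - 1)
  expect_equal(measured, period, tolerance = 1e-3)

  # energy drift below 1e-4 relative over 1e4 steps
  e0 <- fx$backend$evaluate(x0)$energy
  st <- resistmap:::langevin_run(fx$backend, x0, matrix(0, 1, 3), spec, 1e4)
  v2 <- sum(st$v^2)
  e1 <- fx$backend$evaluate(st$x)$energy + 0.5 * m * v2 / 418.4
  expect_lt(abs(e1 - e0) / e0, 1e-4)
})

test_that("thermostatted runs are seed-deterministic and respect fixed atoms", {
  fx <- make_fixture("bead_chain", n_beads = 4)
  spec <- integrator_spec(seed = 77)
  a <- step_langevin(fx$backend, coords(fx$structure), spec = spec, n_steps = 500)
  b <- step_langevin(fx$backend, coords(fx$structure), spec = spec, n_steps = 500)
  expect_identical(a$positions, b$positions)
  expect_identical(a$velocities, b$velocities)

  bk <- fx$backend
  bk$movable_mask[2] <- FALSE
  push <- matrix(0, 4, 3); push[2, 1] <- 50   # kcal/mol/A on the fixed bead
  out <- step_langevin(bk, coords(fx$structure), spec = spec,
                       external_force = push, n_steps = 200)
  expect_identical(out$positions[2, ], coords(fx$structure)[2, ])
})

test_that("generic R loop agrees with the compiled kernel in the Verlet limit", {
  fx <- make_fixture("single_bead")
  adapter <- fx$backend
  adapter$native <- NULL    # force the generic (adapter-route) integrator
  spec <- integrator_spec(friction_ps = 0, temperature_K = 0)
  x0 <- matrix(c(0.3, -0.2, 0.1), 1, 3)
  a <- resistmap:::langevin_run(fx$backend, x0, matrix(0, 1, 3), spec, 2000)
  b <- resistmap:::langevin_run(adapter, x0, matrix(0, 1, 3), spec, 2000)
  expect_equal(a$x, b$x, tolerance = 1e-10)
  expect_equal(a$v, b$v, tolerance = 1e-10)
})

test_that("a tethered bead equilibrates to the equipartition variance", {
  fx <- make_fixture("single_bead", tether_stiffness_pn = 200)
  spec <- integrator_spec(seed = 101)
  out <- resistmap:::langevin_run(fx$backend, coords(fx$structure),
                                  matrix(0, 1, 3), spec, 150000,
                                  sample_every = 10, record_rows = 1L)
  v <- mean(apply(out$traj, 2, var))
  kT <- 8.314462618 / 4184 * 310
  k_kcal <- 200 / pn_per_kcal
  expect_equal(v, kT / k_kcal, tolerance = 0.08)
})
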