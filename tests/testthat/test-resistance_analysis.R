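fake_trace <- function(d, f, residue = 1) {
  structure(list(residue_index = residue, replicate_seed = 0,
                 samples = data.frame(displacement = d, force_pN = f),
                 sampling_interval = 10, pull_spec = NULL),
            class = "fe_trace")
}

test_that("resistance fitting equals closed-form least squares", {
  d <- seq(0, 2.4, length.out = 20)
  expect_equal(fit_resistance(fake_trace(d, 200 * d + 10)), 200)

  set.seed(12)
  f <- 150 * d + 30 + rnorm(20, sd = 25)
  expect_equal(fit_resistance(fake_trace(d, f)), ols_slope_oracle(d, f),
               tolerance = 1e-10)

  # offset invariance and unit linearity
  expect_equal(fit_resistance(fake_trace(d, f + 500)),
               fit_resistance(fake_trace(d, f)), tolerance = 1e-9)
  expect_equal(fit_resistance(fake_trace(d, 3 * f)),
               3 * fit_resistance(fake_trace(d, f)), tolerance = 1e-9)

  # only samples inside the fit range enter the regression
  d2 <- c(d, 3, 4)
  f2 <- c(200 * d + 10, 9999, -9999)
  expect_equal(fit_resistance(fake_trace(d2, f2), fit_range = 2.5), 200)
  expect_error(fit_resistance(fake_trace(c(0, 3, 4), c(0, 1, 2))),
               "insufficient")
})

test_that("replicate aggregation reports mean, SEM and n", {
  expect_equal(aggregate_replicates(c(100, 100, 100)),
               list(mean = 100, sem = 0, n = 3L))
  agg <- aggregate_replicates(c(90, 110))
  expect_equal(agg$mean, 100)
  expect_equal(agg$sem, 10)       # sd = sqrt(200) = 14.142, / sqrt(2)
  expect_warning(one <- aggregate_replicates(250), "single replicate")
  expect_equal(one$sem, 0)
  expect_error(aggregate_replicates(numeric(0)), "no slopes")

  # SEM of draws from N(250, 20^2) sits near 20/sqrt(12)
  set.seed(9)
  sems <- replicate(200, aggregate_replicates(rnorm(12, 250, 20))$sem)
  expect_equal(mean(sems), 20 / sqrt(12), tolerance = 0.1)
})

test_that("classification thresholds are strict at 100 and 300 pN/A", {
  prof <- data.frame(residue_index = 1:5,
                     mean_coefficient = c(99.9, 100, 300, 300.1, 200),
                     sem = 0, n_replicates = 12)
  out <- classify_residues(prof)
  expect_equal(out$class, c("low", "mid", "mid", "high", "mid"))
  same <- classify_residues(data.frame(residue_index = 1:3,
                                       mean_coefficient = rep(150, 3)))
  expect_equal(unique(same$class), "mid")
  expect_error(classify_residues(prof, low = 300, high = 100), "low < high")
})

test_that("patch detection matches a brute-force union-find oracle", {
  # constructed geometry: two tight pairs far apart, plus sub-threshold noise
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(50, 0, 0), c(54, 0, 0), c(100, 0, 0))
  s <- mol_structure(data.frame(
    atom_id = 1:5, atom_name = "CA", element = "C", residue_index = 1:5,
    residue_name = "BEA", chain_id = "A", x = xyz[, 1], y = xyz[, 2],
    z = xyz[, 3], occupancy = 1, bfactor = 0))
  prof <- data.frame(residue_index = 1:5,
                     mean_coefficient = c(400, 350, 320, 500, 90))
  patches <- find_stability_patches(s, prof, patch_threshold = 300)
  expect_length(patches, 2)
  expect_equal(patches[[1]]$residue_indices, c(3, 4))   # highest mean first
  expect_equal(patches[[2]]$residue_indices, c(1, 2))
  expect_equal(patches[[1]]$mean_coefficient, 410)
  expect_length(find_stability_patches(s, prof, patch_threshold = 1000), 0)

  # patches are disjoint and independent of residue ordering
  for (seed in 1:50) {
    cl <- make_random_cluster(30, seed = seed, spread = 8)
    set.seed(seed + 1000)
    vals <- runif(30, 0, 500)
    prof_r <- data.frame(residue_index = 1:30, mean_coefficient = vals)
    got <- find_stability_patches(cl, prof_r, patch_threshold = 250,
                                  linkage_cutoff = 8)
    want <- union_find_patches_oracle(1:30, coords(cl), vals,
                                      threshold = 250, cutoff = 8)
    got_sets <- lapply(got, `[[`, "residue_indices")
    expect_setequal(lapply(got_sets, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
    expect_equal(anyDuplicated(unlist(got_sets)), 0)
    shuf <- prof_r[sample(30), ]
    got2 <- find_stability_patches(cl, shuf, patch_threshold = 250,
                                   linkage_cutoff = 8)
    expect_equal(lapply(got2, `[[`, "residue_indices"), got_sets)
  }
})

test_that("delta profiles use strict 70 pN/A classes and mirror on swap", {
  pa <- data.frame(residue_index = 1:3, mean_coefficient = c(200, 200, 271))
  pb <- data.frame(residue_index = 1:3, mean_coefficient = c(271, 270, 200))
  d <- delta_profile(pa, pb)
  expect_equal(d$class, c("stabilized", "unchanged", "destabilized"))
  expect_equal(d$delta, c(71, 70, -71))
  rev <- delta_profile(pb, pa)
  expect_equal(rev$class, c("destabilized", "unchanged", "stabilized"))
  expect_equal(rev$delta, -d$delta)

  # comparison restricted to shared residues; disjoint sets are an error
  pc <- data.frame(residue_index = 2:4, mean_coefficient = c(100, 100, 100))
  expect_equal(delta_profile(pa, pc)$residue_index, 2:3)
  pd <- data.frame(residue_index = 7:9, mean_coefficient = c(1, 2, 3))
  expect_error(delta_profile(pa, pd), "no residues shared")
})

test_that("Pearson correlation matches the definitional formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  y <- c(2, 1, 4, 3)
  expect_equal(pearson_correlation(x, y), 0.6)
  expect_equal(pearson_correlation(x, y), pearson_oracle(x, y),
               tolerance = 1e-12)
  expect_error(pearson_correlation(x, rep(1, 4)), "zero variance")
  expect_error(pearson_correlation(1:3, 1:4), "equal length")
  expect_error(pearson_correlation(1:2, 2:1), "at least 3")
})
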