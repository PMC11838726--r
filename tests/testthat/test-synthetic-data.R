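test_that("event generator honors degenerate mixtures and rejects bad specs", {
  spec <- population_spec(n_events = 500, frac_trogo = 1, frac_phago = 0,
                          frac_debris = 0, seed = 3)
  ev <- generate_event_table(spec)
  expect_equal(nrow(ev), 500)
  expect_true(all(ev$true_label == "trogo"))

  expect_error(population_spec(frac_trogo = 0.8, frac_phago = 0.4),
               "frac_trogo")
  expect_error(population_spec(frac_debris = 1.5), "frac_debris")
  expect_error(population_spec(gsd = 0.9), "gsd")
})

test_that("event label counts fall in the binomial 99% interval", {
  spec <- population_spec(n_events = 10000, frac_trogo = 0.7,
                          frac_phago = 0.1, frac_debris = 0, seed = 1)
  ev <- generate_event_table(spec)
  cnt <- table(ev$true_label)
  # oracle: binomial quantiles at the generating probabilities
  expect_gte(cnt[["trogo"]], qbinom(0.005, 10000, 0.7))
  expect_lte(cnt[["trogo"]], qbinom(0.995, 10000, 0.7))
  expect_gte(cnt[["phago"]], qbinom(0.005, 10000, 0.1))
  expect_lte(cnt[["phago"]], qbinom(0.995, 10000, 0.1))
})

test_that("generators are deterministic under a fixed seed, to CSV text", {
  spec <- population_spec(n_events = 200, seed = 11)
  a <- generate_event_table(spec)
  b <- generate_event_table(spec)
  expect_identical(a, b)
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write.csv(a, fa, row.names = FALSE); write.csv(b, fb, row.names = FALSE)
  expect_identical(readLines(fa), readLines(fb))
  # generators restore the caller's RNG state
  set.seed(99); before <- .Random.seed
  invisible(generate_event_table(spec))
  expect_identical(.Random.seed, before)
})

test_that("label proportions converge to spec fractions at n = 1e5", {
  spec <- population_spec(n_events = 1e5, frac_trogo = 0.6, frac_phago = 0.2,
                          frac_debris = 0, seed = 5)
  cnt <- table(generate_event_table(spec)$true_label)
  probs <- c(trogo = 0.6, phago = 0.2, unengaged = 0.2)
  for (nm in names(probs)) {
    sd3 <- 3 * sqrt(1e5 * probs[[nm]] * (1 - probs[[nm]]))
    expect_lt(abs(cnt[[nm]] - 1e5 * probs[[nm]]), sd3)
  }
})

test_that("aspiration generator emits Laplace pressures and round-trips", {
  # direct arithmetic: 2 * 1.667e-4 N/m * (4e5 - 1e5) 1/m = 100 Pa
  spec <- aspiration_spec(true_tension = 1 / 6, pipette_radius = 2.5,
                          cell_radius = 10, pressure_noise_sd = 0,
                          n_cells = 5, seed = 1)
  tab <- generate_aspiration_table(spec)
  expect_equal(tab$pressure_pa, rep(100, 5))
  est <- estimate_tensions(tab)
  expect_equal(est$tension_mN_per_m, rep(1 / 6, 5))  # zero-noise identity

  expect_error(aspiration_spec(pipette_radius = 10, cell_radius = 5),
               "pipette_radius")
})

test_that("noisy aspiration tensions are unbiased (3 SE)", {
  spec <- aspiration_spec(true_tension = 0.1, pressure_noise_sd = 5,
                          n_cells = 200, seed = 8)
  est <- estimate_tensions(generate_aspiration_table(spec))
  m <- mean(est$tension_mN_per_m)
  se <- sd(est$tension_mN_per_m) / sqrt(200)
  expect_lt(abs(m - 0.1), 3 * se)
})

test_that("dose-response generator matches the logistic mean structure", {
  spec <- dose_response_spec(a_true = 70, rho_crit_true = 300, d_true = 50,
                             density_grid = 300, n_macrophages_per_well = 2000,
                             n_replicates = 400, seed = 2)
  tab <- generate_dose_response(spec)
  # at x = rho_crit the expected efficiency is a/2
  se <- sqrt(0.35 * 0.65 / 2000) * 100 / sqrt(400)
  expect_lt(abs(mean(tab$efficiency) - 35), 3 * se)
  # logistic limits
  lim <- generate_dose_response(dose_response_spec(
    density_grid = c(0, 1e6), n_replicates = 2, seed = 3))
  expect_true(all(lim$efficiency[lim$density == 1e6] > 60))
  expect_true(all(lim$efficiency[lim$density == 0] < 5))
  expect_error(dose_response_spec(density_grid = numeric(0)), "density_grid")
})

test_that("refitting a generated dose-response recovers rho_crit within 5%", {
  tab <- generate_dose_response(dose_response_spec(seed = 7))
  fit <- fit_sigmoid(tab)
  expect_true(fit$converged)
  expect_lt(abs(fit$rho_crit - 300) / 300, 0.05)
})

test_that("calibration bead generator is linear at zero noise", {
  beads <- generate_calibration_beads(calibration_spec(
    slope = 50, intercept = 0, intensity_cv = 0, seed = 1))
  expect_equal(beads$mesf, 50 * beads$intensity)
})

test_that("bite-size generator is centered on R_min and scales with tension", {
  p <- mechanical_params()  # r_min(0.1, 400) = 1 um
  near_delta <- generate_bite_sizes(bite_size_spec(
    tension = 0.1, density = 400, geometric_sd = 1 + 1e-9, n_bites = 50,
    seed = 4), p)
  expect_equal(near_delta, rep(1, 50), tolerance = 1e-6)

  bites <- generate_bite_sizes(bite_size_spec(
    tension = 0.1, density = 400, geometric_sd = 1.5, n_bites = 500,
    seed = 4), p)
  expect_lt(abs(exp(mean(log(bites))) - 1), 0.05)

  double <- generate_bite_sizes(bite_size_spec(
    tension = 0.2, density = 400, geometric_sd = 1.5, n_bites = 500,
    seed = 4), p)
  expect_equal(median(double), 2 * median(bites))
})
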