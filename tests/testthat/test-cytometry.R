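test_that("thresholds come from the right control at the right quantile", {
  ctrl <- make_controls(n = 4000, seed = 42)
  # degenerate background: constant red -> threshold equals it
  mac_const <- ctrl$mac
  mac_const$red <- 123
  g <- derive_thresholds(mac_const, ctrl$tgt)
  expect_equal(g$red_thr, 123)

  g995 <- derive_thresholds(ctrl$mac, ctrl$tgt, quantile = 0.995)
  # by construction of the quantile, <= 0.5% of background exceeds it
  expect_lte(mean(ctrl$mac$orange > g995$orange_thr), 0.005 + 1e-9)
  expect_lte(mean(ctrl$mac$red > g995$red_thr), 0.005 + 1e-9)
  expect_lte(mean(ctrl$tgt$green > g995$green_thr), 0.005 + 1e-9)

  # thresholds monotone non-decreasing in the quantile
  g99 <- derive_thresholds(ctrl$mac, ctrl$tgt, quantile = 0.99)
  expect_true(all(c(g99$green_thr <= g995$green_thr,
                    g99$orange_thr <= g995$orange_thr,
                    g99$red_thr <= g995$red_thr)))

  expect_error(derive_thresholds(ctrl$mac[0, ], ctrl$tgt), "macrophage")
  expect_error(derive_thresholds(ctrl$mac, ctrl$tgt[0, ]), "target")
})

test_that("classification implements the stated fluorescence logic", {
  gates <- structure(list(green_thr = 10, orange_thr = 10, red_thr = 10,
                          method = "fixed", quantile = NA),
                     class = "gate_thresholds")
  ev <- data.frame(green = c(100, 1, 100, 100, 100),
                   orange = c(100, 1, 1, 1, 100),
                   red = c(100, 1, 100, 1, 1))
  lab <- classify_events(ev, gates)$label
  expect_equal(lab, c("phago",      # green+/red+/orange+
                      "debris",     # below all thresholds
                      "trogo",      # green+/red+/orange-
                      "unengaged",  # green+ only
                      "unengaged")) # green+/orange+/red-: undefined cell
})

test_that("labels partition the table for arbitrary thresholds", {
  ev <- generate_event_table(population_spec(n_events = 2000, seed = 9,
                                             frac_debris = 0.2))
  set.seed(14)
  for (i in 1:20) {
    gates <- structure(list(green_thr = runif(1, 1, 5000),
                            orange_thr = runif(1, 1, 5000),
                            red_thr = runif(1, 1, 5000)),
                       class = "gate_thresholds")
    lab <- classify_events(ev, gates)$label
    expect_equal(sum(table(lab)), nrow(ev))
    expect_true(all(lab %in% c("debris", "unengaged", "trogo", "phago")))
  }
})

test_that("misclassification decreases as signal/background separation grows", {
  err_at <- function(sep) {
    ev <- generate_event_table(population_spec(
      n_events = 5000, frac_trogo = 0.5, frac_phago = 0.3, frac_debris = 0.1,
      signal_gm = 100 * sep, seed = 21))
    ctrl <- list(
      mac = generate_event_table(population_spec(
        n_events = 4000, frac_trogo = 0, frac_phago = 0, frac_debris = 0,
        signal_gm = 100 * sep, seed = 22)),
      tgt = generate_event_table(population_spec(
        n_events = 4000, frac_trogo = 0, frac_phago = 0, frac_debris = 1,
        signal_gm = 100 * sep, seed = 23)))
    gates <- derive_thresholds(ctrl$mac, ctrl$tgt)
    mean(classify_events(ev, gates)$label != ev$true_label)
  }
  errs <- vapply(c(5, 20, 100), err_at, numeric(1))
  expect_true(all(diff(errs) <= 0))
  expect_lt(errs[2], 0.01)
})

test_that("efficiencies are percentages of all green-positive events", {
  r <- compute_efficiencies(counts_table(trogo = 7, phago = 1, unengaged = 2,
                                         debris = 5))
  expect_equal(r$n_total_macrophage, 10)
  expect_equal(r$trogo_eff, 70)
  expect_equal(r$phago_eff, 10)

  r0 <- compute_efficiencies(counts_table(unengaged = 4))
  expect_equal(r0$trogo_eff, 0)
  expect_equal(r0$phago_eff, 0)

  expect_error(compute_efficiencies(counts_table(debris = 3)), "no CellTracker")
  expect_error(compute_efficiencies(data.frame(green = 1)), "label")
})

test_that("replicate summary uses the sample SD and ignores ordering", {
  d <- data.frame(condition = "a", trogo_eff = c(70, 70, 70),
                  phago_eff = c(10, 10, 10))
  s <- replicate_summary(d)
  expect_equal(s$trogo_mean, 70)
  expect_equal(s$trogo_sd, 0)

  d2 <- data.frame(condition = "a", trogo_eff = c(60, 70, 80),
                   phago_eff = c(5, 10, 15))
  s2 <- replicate_summary(d2)
  expect_equal(s2$trogo_mean, 70)
  expect_equal(s2$trogo_sd, 10)  # sample SD, n-1 denominator
  expect_equal(replicate_summary(d2[c(3, 1, 2), ]), s2)

  s1 <- replicate_summary(d2[1, ])
  expect_true(is.na(s1$trogo_sd))
})

test_that("the efficiency estimator is unbiased on ground-truth labels", {
  # isolates compute_efficiencies() from gating noise: labels come from the
  # generator, so the estimator is a plain binomial proportion
  effs <- vapply(1:200, function(s) {
    ev <- generate_event_table(population_spec(
      n_events = 2000, frac_trogo = 0.7, frac_phago = 0.1, frac_debris = 0,
      seed = 1000 + s))
    ev$label <- ev$true_label
    compute_efficiencies(ev)$trogo_eff
  }, numeric(1))
  se <- sd(effs) / sqrt(200)
  expect_lt(abs(mean(effs) - 70), 3 * se)
})
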