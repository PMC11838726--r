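# Shared fixture builders. Everything is generated in code; no stored data.

# Noiseless dose-response table from the generating logistic.
noiseless_dose_table <- function(a = 70, rho_crit = 300, d = 50,
                                 densities = c(0, 50, 100, 150, 200, 250,
                                               300, 400, 600, 1000)) {
  data.frame(density = densities,
             efficiency = a * plogis((densities - rho_crit) / d))
}

# A labeled event table with given class counts (intensities irrelevant).
counts_table <- function(trogo = 0, phago = 0, unengaged = 0, debris = 0) {
  data.frame(label = rep(c("trogo", "phago", "unengaged", "debris"),
                         times = c(trogo, phago, unengaged, debris)))
}

# Well-separated synthetic controls for threshold derivation.
make_controls <- function(n = 5000, seed = 42) {
  list(
    mac = generate_event_table(population_spec(
      n_events = n, frac_trogo = 0, frac_phago = 0, frac_debris = 0,
      sample = "mac_only", seed = seed)),
    tgt = generate_event_table(population_spec(
      n_events = n, frac_trogo = 0, frac_phago = 0, frac_debris = 1,
      sample = "target_only", seed = seed + 1))
  )
}
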