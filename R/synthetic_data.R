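#' @name synthetic-data
#' @title Synthetic-data generators with known ground truth
#'
#' @description
#' Every input the pipeline consumes can be generated here with known
#' generating parameters: per-event three-channel flow-cytometry tables,
#' micropipette aspiration pressure records, MESF calibration bead tables,
#' sigmoid dose-response efficiency tables, and trogocytic bite-size samples.
#' All randomness flows from the single integer `seed` carried by each spec;
#' the caller's RNG state is never touched.
NULL

#' Specification of a synthetic cytometry event population
#'
#' Describes a mixture of macrophage events: a `frac_debris` fraction are
#' CellTracker-negative debris; the remainder are trogocytic
#' (green+/red+/orange-), phagocytic (green+/red+/orange+), or unengaged
#' (green+ only) with probabilities `frac_trogo`, `frac_phago`, and the
#' complement. Channel intensities are lognormal with per-channel geometric
#' means (`background_gm` for negative channels, `signal_gm` for positive)
#' and geometric standard deviation `gsd`.
#'
#' @param n_events number of events to generate.
#' @param frac_trogo,frac_phago fractions of non-debris events that are
#'   trogocytic / phagocytic; must sum to at most 1.
#' @param frac_debris fraction of CellTracker-negative (green-) events.
#' @param background_gm,signal_gm per-channel geometric means (arbitrary
#'   fluorescence units), length 3 in order (green, orange, red) or a scalar.
#'   Default separation is 20x, which with `gsd = 1.5` gives essentially
#'   non-overlapping positive/negative populations.
#' @param gsd per-channel geometric standard deviation (> 1), length 3 or
#'   scalar.
#' @param sample sample label written into the table.
#' @param seed integer seed; all randomness derives from it.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_events = 10000L, frac_trogo = 0.7,
                            frac_phago = 0.1, frac_debris = 0,
                            background_gm = 100, signal_gm = 2000,
                            gsd = 1.5, sample = "S1", seed = 1L) {
  if (!is.numeric(n_events) || length(n_events) != 1L || n_events < 1) {
    stop_field("n_events", "must be a positive count")
  }
  check_fraction(frac_trogo, "frac_trogo")
  check_fraction(frac_phago, "frac_phago")
  check_fraction(frac_debris, "frac_debris")
  if (frac_trogo + frac_phago > 1) {
    stop_field("frac_trogo", "frac_trogo + frac_phago must be <= 1")
  }
  background_gm <- rep_len(background_gm, 3L)
  signal_gm <- rep_len(signal_gm, 3L)
  gsd <- rep_len(gsd, 3L)
  check_positive(background_gm, "background_gm")
  check_positive(signal_gm, "signal_gm")
  if (any(gsd <= 1)) stop_field("gsd", "geometric SD must be > 1")
  structure(list(n_events = as.integer(n_events), frac_trogo = frac_trogo,
                 frac_phago = frac_phago, frac_debris = frac_debris,
                 background_gm = background_gm, signal_gm = signal_gm,
                 gsd = gsd, sample = sample, seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a synthetic flow-cytometry event table
#'
#' Draws event class labels from the spec's mixture and lognormal channel
#' intensities conditional on class. The ground-truth label is retained in a
#' `true_label` column for testing; the classifier never sees it.
#'
#' @param spec a [population_spec()].
#' @return a `data.frame` with columns `event_id`, `green` (CellTracker),
#'   `orange` (pHrodo), `red` (AF647 antibody), `sample`, `true_label`.
#' @export
generate_event_table <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_events
  with_seed(spec$seed, {
    debris <- stats::runif(n) < spec$frac_debris
    p_rest <- c(trogo = spec$frac_trogo, phago = spec$frac_phago,
                unengaged = 1 - spec$frac_trogo - spec$frac_phago)
    label <- rep("debris", n)
    n_rest <- sum(!debris)
    if (n_rest > 0) {
      label[!debris] <- sample(names(p_rest), n_rest, replace = TRUE,
                               prob = p_rest)
    }
    # Channel truth table: rows = class, cols = (green, orange, red);
    # TRUE = signal-level geometric mean, FALSE = background.
    pos <- rbind(debris    = c(FALSE, FALSE, FALSE),
                 unengaged = c(TRUE, FALSE, FALSE),
                 trogo     = c(TRUE, FALSE, TRUE),
                 phago     = c(TRUE, TRUE, TRUE))
    draw_channel <- function(ch) {
      gm <- ifelse(pos[label, ch], spec$signal_gm[ch], spec$background_gm[ch])
      stats::rlnorm(n, meanlog = log(gm), sdlog = log(spec$gsd[ch]))
    }
    data.frame(event_id = seq_len(n),
               green = draw_channel(1L),
               orange = draw_channel(2L),
               red = draw_channel(3L),
               sample = spec$sample,
               true_label = label,
               stringsAsFactors = FALSE)
  })
}

#' Specification of synthetic micropipette aspiration measurements
#'
#' @param true_tension generating interfacial tension gamma, mN/m.
#' @param pipette_radius,cell_radius pipette and cell radii, um; the pipette
#'   must be narrower than the cell for a valid Laplace estimate.
#' @param pressure_noise_sd Gaussian noise SD added to the suction pressure,
#'   Pa.
#' @param n_cells number of measurement records.
#' @param sample_prefix prefix for generated sample ids.
#' @param seed integer seed.
#' @return an object of class `aspiration_spec`.
#' @export
aspiration_spec <- function(true_tension = 0.1, pipette_radius = 2.5,
                            cell_radius = 10, pressure_noise_sd = 5,
                            n_cells = 20L, sample_prefix = "cell",
                            seed = 1L) {
  check_positive(true_tension, "true_tension")
  check_positive(pipette_radius, "pipette_radius")
  check_positive(cell_radius, "cell_radius")
  if (pipette_radius >= cell_radius) {
    stop_field("pipette_radius", "must be smaller than cell_radius")
  }
  if (pressure_noise_sd < 0) stop_field("pressure_noise_sd", "must be >= 0")
  structure(list(true_tension = true_tension,
                 pipette_radius = pipette_radius, cell_radius = cell_radius,
                 pressure_noise_sd = pressure_noise_sd,
                 n_cells = as.integer(n_cells),
                 sample_prefix = sample_prefix, seed = as.integer(seed)),
            class = "aspiration_spec")
}

#' Generate synthetic aspiration measurements from the Laplace law
#'
#' Each record's suction pressure is the exact Young-Laplace pressure
#' `2 * gamma * (1/R_pipette - 1/R_cell)` for the spec's tension plus
#' Gaussian noise. At zero noise, [laplace_tension()] recovers the generating
#' tension exactly.
#'
#' @param spec an [aspiration_spec()].
#' @return a `data.frame` with columns `sample_id`, `pressure_pa`,
#'   `r_pipette_um`, `r_cell_um`, `tongue_um`.
#' @export
generate_aspiration_table <- function(spec) {
  stopifnot(inherits(spec, "aspiration_spec"))
  gamma_si <- spec$true_tension * .MN_PER_M_TO_N_PER_M
  curv <- 1 / (spec$pipette_radius * .UM_TO_M) - 1 / (spec$cell_radius * .UM_TO_M)
  dp <- 2 * gamma_si * curv
  with_seed(spec$seed, {
    noise <- if (spec$pressure_noise_sd > 0) {
      stats::rnorm(spec$n_cells, 0, spec$pressure_noise_sd)
    } else rep(0, spec$n_cells)
    data.frame(sample_id = paste0(spec$sample_prefix, seq_len(spec$n_cells)),
               pressure_pa = dp + noise,
               r_pipette_um = spec$pipette_radius,
               r_cell_um = spec$cell_radius,
               tongue_um = spec$pipette_radius,
               stringsAsFactors = FALSE)
  })
}

#' Specification of a synthetic dose-response experiment
#'
#' The generating model is a logistic in antibody surface density: the
#' per-macrophage trogocytosis probability at density x is
#' `a_true/100 * plogis((x - rho_crit_true) / d_true)`; each well observes a
#' binomially sampled efficiency over `n_macrophages_per_well` macrophages.
#'
#' @param a_true plateau efficiency, percent (0, 100].
#' @param rho_crit_true inflection-point density, antibodies/um^2.
#' @param d_true transition width, antibodies/um^2.
#' @param density_grid antibody densities assayed, antibodies/um^2.
#' @param n_macrophages_per_well macrophages counted per well.
#' @param n_replicates biological replicates per density.
#' @param condition condition label.
#' @param seed integer seed.
#' @return an object of class `dose_response_spec`.
#' @export
dose_response_spec <- function(a_true = 70, rho_crit_true = 300, d_true = 50,
                               density_grid = c(0, 50, 100, 150, 200, 250,
                                                300, 400, 600, 1000),
                               n_macrophages_per_well = 1000L,
                               n_replicates = 3L, condition = "cond",
                               seed = 1L) {
  if (!is.numeric(a_true) || a_true <= 0 || a_true > 100) {
    stop_field("a_true", "must be in (0, 100]")
  }
  check_positive(rho_crit_true, "rho_crit_true")
  check_positive(d_true, "d_true")
  if (length(density_grid) == 0) stop_field("density_grid", "must be non-empty")
  if (any(density_grid < 0)) stop_field("density_grid", "densities must be >= 0")
  structure(list(a_true = a_true, rho_crit_true = rho_crit_true,
                 d_true = d_true, density_grid = as.numeric(density_grid),
                 n_macrophages_per_well = as.integer(n_macrophages_per_well),
                 n_replicates = as.integer(n_replicates),
                 condition = condition, seed = as.integer(seed)),
            class = "dose_response_spec")
}

#' Generate a synthetic dose-response table
#'
#' @param spec a [dose_response_spec()].
#' @return a `data.frame` with columns `density`, `efficiency` (percent),
#'   `replicate`, `condition`.
#' @export
generate_dose_response <- function(spec) {
  stopifnot(inherits(spec, "dose_response_spec"))
  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      density = spec$density_grid)
  p <- spec$a_true / 100 *
    stats::plogis((grid$density - spec$rho_crit_true) / spec$d_true)
  with_seed(spec$seed, {
    k <- stats::rbinom(nrow(grid), spec$n_macrophages_per_well, p)
    data.frame(density = grid$density,
               efficiency = 100 * k / spec$n_macrophages_per_well,
               replicate = grid$replicate,
               condition = spec$condition,
               stringsAsFactors = FALSE)
  })
}

#' Specification of synthetic MESF calibration beads
#'
#' Bead populations with known fluorophore counts (MESF) and intensities on
#' a linear intensity scale: `intensity = (mesf - intercept) / slope`, with
#' multiplicative lognormal measurement noise on intensity.
#'
#' @param slope fluorophores per intensity unit of the generating line.
#' @param intercept fluorophores at zero intensity.
#' @param mesf_levels known fluorophore counts of the bead populations.
#' @param n_per_level beads measured per population.
#' @param intensity_cv coefficient of variation of bead intensity (lognormal).
#' @param seed integer seed.
#' @return an object of class `calibration_spec`.
#' @export
calibration_spec <- function(slope = 50, intercept = 0,
                             mesf_levels = c(1e4, 5e4, 2e5, 8e5),
                             n_per_level = 50L, intensity_cv = 0.05,
                             seed = 1L) {
  check_positive(slope, "slope")
  check_positive(mesf_levels, "mesf_levels")
  if (length(mesf_levels) < 2) stop_field("mesf_levels", "need >= 2 levels")
  if (intensity_cv < 0) stop_field("intensity_cv", "must be >= 0")
  structure(list(slope = slope, intercept = intercept,
                 mesf_levels = as.numeric(mesf_levels),
                 n_per_level = as.integer(n_per_level),
                 intensity_cv = intensity_cv, seed = as.integer(seed)),
            class = "calibration_spec")
}

#' Generate a synthetic MESF bead table
#'
#' @param spec a [calibration_spec()].
#' @return a `data.frame` with columns `intensity`, `mesf`.
#' @export
generate_calibration_beads <- function(spec) {
  stopifnot(inherits(spec, "calibration_spec"))
  mesf <- rep(spec$mesf_levels, each = spec$n_per_level)
  mu <- (mesf - spec$intercept) / spec$slope
  with_seed(spec$seed, {
    intensity <- if (spec$intensity_cv > 0) {
      sdlog <- sqrt(log1p(spec$intensity_cv^2))
      mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog)
    } else mu
    data.frame(intensity = intensity, mesf = mesf)
  })
}

#' Specification of synthetic trogocytic bite sizes
#'
#' @param tension target tension, mN/m.
#' @param density antibody surface density, antibodies/um^2.
#' @param geometric_sd lognormal geometric SD of bite diameters (> 1).
#' @param n_bites number of bites sampled.
#' @param seed integer seed.
#' @return an object of class `bite_size_spec`.
#' @export
bite_size_spec <- function(tension = 0.1, density = 400, geometric_sd = 1.5,
                           n_bites = 500L, seed = 1L) {
  check_positive(tension, "tension")
  check_positive(density, "density")
  if (geometric_sd <= 1) stop_field("geometric_sd", "must be > 1")
  structure(list(tension = tension, density = density,
                 geometric_sd = geometric_sd, n_bites = as.integer(n_bites),
                 seed = as.integer(seed)),
            class = "bite_size_spec")
}

#' Generate synthetic bite diameters around the scaling-law prediction
#'
#' Samples lognormal diameters whose median equals the minimum deformation
#' scale `R_min(tension, density)` predicted by [r_min()] under `params`.
#' Because the lognormal is multiplicative, doubling the spec tension at a
#' fixed seed exactly doubles every sampled diameter.
#'
#' @param spec a [bite_size_spec()].
#' @param params a [mechanical_params()].
#' @return numeric vector of bite diameters, um.
#' @export
generate_bite_sizes <- function(spec, params = mechanical_params()) {
  stopifnot(inherits(spec, "bite_size_spec"))
  med <- r_min(spec$tension, spec$density, params)
  with_seed(spec$seed, {
    stats::rlnorm(spec$n_bites, meanlog = log(med),
                  sdlog = log(spec$geometric_sd))
  })
}
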