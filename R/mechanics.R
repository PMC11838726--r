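#' Parameters of the interfacial force-balance scaling model
#'
#' The model balances antibody-dependent active normal stress against target
#' tension at the macrophage-target interface. Active stress is assumed
#' linear in antibody density and is calibrated by the pair
#' (`sigma_ref`, `rho_ref`): the stress at density `rho` is
#' `sigma_ref * rho / rho_ref`. Defaults reflect measured orders of
#' magnitude: 100 Pa normal stress at ~400 antibodies/um^2, an interface
#' size of ~1 um, a lipid-bilayer bending stiffness of 1e-19 J, and a
#' minimum engagement density of ~100 antibodies/um^2 below which no
#' FcR-driven response occurs.
#'
#' @param sigma_ref active normal stress at the reference density, Pa.
#' @param rho_ref reference antibody density, antibodies/um^2.
#' @param interface_radius macrophage-target interface size R, um.
#' @param bending_stiffness membrane bending stiffness kappa, J.
#' @param rho_min engagement-floor antibody density, antibodies/um^2.
#' @return an object of class `mechanical_params`.
#' @export
mechanical_params <- function(sigma_ref = 100, rho_ref = 400,
                              interface_radius = 1,
                              bending_stiffness = 1e-19, rho_min = 100) {
  check_positive(sigma_ref, "sigma_ref")
  check_positive(rho_ref, "rho_ref")
  check_positive(interface_radius, "interface_radius")
  check_positive(bending_stiffness, "bending_stiffness")
  check_positive(rho_min, "rho_min")
  structure(list(sigma_ref = sigma_ref, rho_ref = rho_ref,
                 interface_radius = interface_radius,
                 bending_stiffness = bending_stiffness, rho_min = rho_min),
            class = "mechanical_params")
}

#' Antibody-dependent active normal stress
#'
#' `sigma_eff(rho) = sigma_ref * rho / rho_ref` — active stresses scale
#' linearly with the antibody density on the target.
#'
#' @param rho antibody density, antibodies/um^2 (vectorized).
#' @param params a [mechanical_params()].
#' @return stress, Pa.
#' @export
effective_stress <- function(rho, params = mechanical_params()) {
  stopifnot(inherits(params, "mechanical_params"))
  if (any(rho < 0, na.rm = TRUE)) stop_field("rho", "must be >= 0")
  params$sigma_ref * rho / params$rho_ref
}

#' Minimum deformation scale of the target membrane
#'
#' The balance of active normal stress against target tension over a
#' deformation of size R gives `R_min = gamma / sigma_eff(rho)` (the
#' dimensionless prefactor of the scaling law is taken as 1). Below R_min,
#' tension damps out active fluctuations; R_min is therefore the predicted
#' scale of trogocytic bites.
#'
#' @param gamma target cortical or membrane tension, mN/m (vectorized).
#' @param rho antibody density, antibodies/um^2 (vectorized).
#' @param params a [mechanical_params()].
#' @return minimum deformation scale, um. `Inf` where `rho = 0` (no active
#'   stress).
#' @examples
#' r_min(0.1, 400)   # 1 um at 100 Pa effective stress
#' r_min(0.01, 400)  # 0.1 um
#' @export
r_min <- function(gamma, rho, params = mechanical_params()) {
  sig <- effective_stress(rho, params)                 # Pa
  out <- (gamma * .MN_PER_M_TO_N_PER_M) / sig / .UM_TO_M
  out[sig == 0] <- Inf
  out
}

#' Bending-limited deformation scale
#'
#' Balancing active stress against membrane bending gives a second length
#' scale; in the pressure-balance form used here,
#' `l_bend = (kappa / sigma_eff)^(1/3)`. For physiological tensions and
#' bending stiffnesses this is smaller than `R_min`, so tension sets the
#' bite scale.
#'
#' @inheritParams r_min
#' @param exponent exponent of the balance, default 1/3 (configurable since
#'   the underlying derivation admits alternative forms).
#' @return bending length scale, um.
#' @export
l_bend <- function(rho, params = mechanical_params(), exponent = 1 / 3) {
  sig <- effective_stress(rho, params)
  (params$bending_stiffness / sig)^exponent / .UM_TO_M
}

#' Classify the predicted macrophage behavior
#'
#' Below the engagement floor `rho_min` there is no response. Otherwise the
#' behavior is trogocytosis when the minimum deformation scale is strictly
#' smaller than the interface (`R_min < R`: bites can pinch off inside the
#' contact), and phagocytosis when it is not (the boundary `R_min = R` is
#' labeled phagocytosis).
#'
#' @inheritParams r_min
#' @return character vector: `"no_engagement"`, `"trogocytosis"`, or
#'   `"phagocytosis"`.
#' @export
classify_regime <- function(gamma, rho, params = mechanical_params()) {
  n <- max(length(gamma), length(rho))
  gamma <- rep_len(gamma, n)
  rho <- rep_len(rho, n)
  out <- ifelse(rho < params$rho_min, "no_engagement",
                ifelse(r_min(gamma, rho, params) < params$interface_radius,
                       "trogocytosis", "phagocytosis"))
  out
}

#' Critical antibody density at a given tension
#'
#' The density at which `R_min` equals the interface size:
#' `rho_crit(gamma) = rho_ref * gamma / (sigma_ref * R)` — linear in tension
#' through the origin. Above it (bites smaller than the interface) the model
#' predicts trogocytosis; below it, phagocytosis.
#'
#' @inheritParams r_min
#' @return critical density, antibodies/um^2.
#' @export
critical_density <- function(gamma, params = mechanical_params()) {
  check_positive(gamma, "gamma")
  params$rho_ref * (gamma * .MN_PER_M_TO_N_PER_M) /
    (params$sigma_ref * params$interface_radius * .UM_TO_M)
}

#' Critical tension at a given antibody density
#'
#' The inverse of [critical_density()]:
#' `gamma_crit(rho) = sigma_eff(rho) * R`, in mN/m. Targets above this
#' tension are phagocytosed, below it trogocytosed.
#'
#' @inheritParams r_min
#' @return critical tension, mN/m.
#' @export
critical_tension <- function(rho, params = mechanical_params()) {
  check_positive(rho, "rho")
  effective_stress(rho, params) * (params$interface_radius * .UM_TO_M) /
    .MN_PER_M_TO_N_PER_M
}

#' Phase diagram of predicted macrophage behavior
#'
#' Classifies every (tension, density) cell of the outer grid and reports
#' the analytic boundaries: the trogocytosis/phagocytosis line
#' `rho_crit(gamma)` and the engagement floor `rho = rho_min`.
#'
#' @param gamma_grid tensions, mN/m.
#' @param rho_grid antibody densities, antibodies/um^2.
#' @param params a [mechanical_params()].
#' @return an object of class `phase_diagram`: list with `grid` (long-format
#'   data.frame: `gamma`, `rho`, `r_min_um`, `l_bend_um`, `regime`),
#'   `boundary` (`gamma`, `rho_crit`), `rho_min`, `params`.
#' @export
phase_diagram <- function(gamma_grid, rho_grid, params = mechanical_params()) {
  check_positive(gamma_grid, "gamma_grid")
  check_positive(rho_grid, "rho_grid")
  g <- expand.grid(gamma = gamma_grid, rho = rho_grid)
  grid <- data.frame(gamma = g$gamma, rho = g$rho,
                     r_min_um = r_min(g$gamma, g$rho, params),
                     l_bend_um = l_bend(g$rho, params),
                     regime = classify_regime(g$gamma, g$rho, params),
                     stringsAsFactors = FALSE)
  boundary <- data.frame(gamma = sort(unique(gamma_grid)),
                         rho_crit = critical_density(sort(unique(gamma_grid)),
                                                     params))
  structure(list(grid = grid, boundary = boundary, rho_min = params$rho_min,
                 params = params),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  tab <- table(x$grid$regime)
  cat(sprintf("phase diagram: %d x %d grid\n",
              length(unique(x$grid$gamma)), length(unique(x$grid$rho))))
  for (r in names(tab)) cat(sprintf("  %-14s %d cells\n", r, tab[[r]]))
  invisible(x)
}

#' Plot a phase diagram
#'
#' Base-graphics rendering: regime regions on log-log axes with the
#' analytic boundary curves overlaid.
#'
#' @param x a `phase_diagram`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.phase_diagram <- function(x, ...) {
  cols <- c(no_engagement = "grey80", phagocytosis = "#7698c3",
            trogocytosis = "#c38a76")
  g <- x$grid
  graphics::plot(g$gamma, g$rho, col = cols[g$regime], pch = 15, cex = 0.6,
                 log = "xy", xlab = "tension (mN/m)",
                 ylab = expression(rho[AB] ~ (antibodies / mu * m^2)), ...)
  graphics::lines(x$boundary$gamma, pmax(x$boundary$rho_crit, x$rho_min),
                  lwd = 2)
  graphics::abline(h = x$rho_min, lty = 2)
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 15,
                   bg = "white", cex = 0.8)
  invisible(x)
}

#' Compare measured bite sizes with the scaling prediction
#'
#' @param measured_um measured bite diameters, um.
#' @param predicted_r_min_um predicted minimum deformation scale, um.
#' @return list with `geometric_mean_um`, `ratio` (geometric mean of
#'   measured / predicted), and `order_of_magnitude_agreement` (`TRUE` when
#'   the ratio lies in [0.1, 10]).
#' @export
compare_bite_sizes <- function(measured_um, predicted_r_min_um) {
  if (length(measured_um) == 0) stop("no measured bite sizes", call. = FALSE)
  check_positive(measured_um, "measured_um")
  check_positive(predicted_r_min_um, "predicted_r_min_um")
  gm <- geometric_mean(measured_um)
  ratio <- gm / predicted_r_min_um
  list(geometric_mean_um = gm, ratio = ratio,
       order_of_magnitude_agreement = ratio >= 0.1 && ratio <= 10)
}
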