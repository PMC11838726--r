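#' Fit a MESF calibration curve
#'
#' Ordinary least squares of known fluorophore count (MESF) on measured bead
#' intensity. MESF kits are close to linear on the raw intensity scale, so
#' no transform is applied.
#'
#' @param beads a `data.frame` with columns `intensity` and `mesf`.
#' @return an object of class `calibration_curve`: list with `slope`
#'   (fluorophores per intensity unit), `intercept` (fluorophores),
#'   `r_squared`, `n_beads`.
#' @export
fit_calibration <- function(beads) {
  if (!all(c("intensity", "mesf") %in% names(beads))) {
    stop("bead table needs `intensity` and `mesf` columns", call. = FALSE)
  }
  if (nrow(beads) < 2) stop("need at least 2 bead records", call. = FALSE)
  if (stats::var(beads$intensity) == 0) {
    stop("bead intensities have zero variance; cannot calibrate",
         call. = FALSE)
  }
  fit <- stats::lm(mesf ~ intensity, data = beads)
  ss_tot <- sum((beads$mesf - mean(beads$mesf))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_beads = nrow(beads)),
            class = "calibration_curve")
}

#' Convert fluorescence intensity to antibody surface density
#'
#' Maps intensity to fluorophore count through the calibration curve,
#' divides by the fluorophores carried per IgG, and normalizes by the
#' spherical surface area `pi * diameter^2` of the cell or vesicle:
#' \deqn{\rho_{AB} = \frac{(s \cdot I + b) / f_{IgG}}{\pi D^2}}
#'
#' @param intensity measured intensity (background-subtracted if
#'   `background_intensity` is supplied), vectorized.
#' @param curve a `calibration_curve` from [fit_calibration()].
#' @param fluorophores_per_igg fluorophores per antibody; commercial labeled
#'   IgG carries 5-7, default 6.
#' @param diameter_um cell or vesicle diameter, um (a per-cell-type average,
#'   not estimated here).
#' @param sample_id optional labels.
#' @param background_intensity autofluorescence intensity subtracted before
#'   conversion, default 0.
#' @return a `data.frame` of class `density_estimate` with columns
#'   `sample_id`, `antibodies_per_um2`, `igg_count`, `fluorophores`,
#'   `qc_flag` (`"below_calibration_range"` when the predicted fluorophore
#'   count is non-positive, in which case the density is `NA`).
#' @examples
#' curve <- fit_calibration(data.frame(intensity = 1:4 * 1e3,
#'                                     mesf = 1:4 * 5e4))
#' intensity_to_density(753982 / 50, curve, 6, 10)  # ~400 antibodies/um^2
#' @export
intensity_to_density <- function(intensity, curve, fluorophores_per_igg = 6,
                                 diameter_um, sample_id = NULL,
                                 background_intensity = 0) {
  stopifnot(inherits(curve, "calibration_curve"))
  check_positive(fluorophores_per_igg, "fluorophores_per_igg")
  check_positive(diameter_um, "diameter_um")
  fluor <- curve$slope * (intensity - background_intensity) + curve$intercept
  bad <- !(fluor > 0)
  igg <- fluor / fluorophores_per_igg
  area <- pi * diameter_um^2                       # sphere surface, um^2
  dens <- igg / area
  dens[bad] <- NA_real_
  n <- length(intensity)
  if (is.null(sample_id)) sample_id <- paste0("c", seq_len(n))
  out <- data.frame(sample_id = rep_len(sample_id, n),
                    antibodies_per_um2 = dens,
                    igg_count = ifelse(bad, NA_real_, igg),
                    fluorophores = fluor,
                    qc_flag = ifelse(bad, "below_calibration_range", "ok"),
                    stringsAsFactors = FALSE)
  class(out) <- c("density_estimate", "data.frame")
  out
}

#' Check a measured density against a target coverage window
#'
#' Experiments matching antibody surface coverage across cell types accept a
#' measurement within a relative tolerance of the target (e.g. 300-500
#' antibodies/um^2 around a 400 target at 25 percent).
#'
#' @param target_density target, antibodies/um^2.
#' @param measured_density measured value(s), antibodies/um^2.
#' @param tolerance relative tolerance, default 0.25.
#' @return logical vector: `TRUE` when within
#'   `[target * (1 - tol), target * (1 + tol)]`.
#' @export
match_density <- function(target_density, measured_density, tolerance = 0.25) {
  check_positive(target_density, "target_density")
  measured_density >= target_density * (1 - tolerance) &
    measured_density <= target_density * (1 + tolerance)
}
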