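#' Interfacial tension from micropipette aspiration (Young-Laplace law)
#'
#' Converts a suction-pressure measurement and the pipette/cell geometry into
#' an interfacial (cortical or membrane) tension:
#' \deqn{\gamma = \frac{\Delta P_{suction}}{2 (1/R_{pipette} - 1/R_{cell})}}
#' Internally SI; the result is reported in mN/m. The estimate is invariant
#' to the length unit provided both radii use the same one.
#'
#' @param pressure_pa suction pressure, Pa (vectorized).
#' @param r_pipette_um pipette inner radius, um.
#' @param r_cell_um radius of the un-aspirated spherical portion of the cell
#'   (or GUV), um.
#' @param sample_id optional sample labels.
#' @param radius_unit unit of the two radii, `"um"` (default) or `"m"`.
#' @return a `data.frame` of class `tension_estimate` with columns
#'   `sample_id`, `tension_mN_per_m`, `qc_flag`. `qc_flag` is
#'   `"invalid_geometry"` (tension `NA`) when the pipette is not narrower
#'   than the cell; zero pressure gives zero tension with flag `"ok"`.
#' @examples
#' laplace_tension(100, 2.5, 10)  # 0.1667 mN/m
#' @export
laplace_tension <- function(pressure_pa, r_pipette_um, r_cell_um,
                            sample_id = NULL, radius_unit = c("um", "m")) {
  radius_unit <- match.arg(radius_unit)
  n <- max(length(pressure_pa), length(r_pipette_um), length(r_cell_um))
  pressure_pa <- rep_len(pressure_pa, n)
  r_pipette_um <- rep_len(r_pipette_um, n)
  r_cell_um <- rep_len(r_cell_um, n)
  if (is.null(sample_id)) sample_id <- paste0("m", seq_len(n))
  to_m <- if (radius_unit == "um") .UM_TO_M else 1
  rp <- r_pipette_um * to_m
  rc <- r_cell_um * to_m
  bad <- !is.finite(rp) | rp <= 0 | !(rp < rc)
  curv <- 1 / rp - 1 / rc                      # 1/m; > 0 when geometry valid
  gamma <- pressure_pa / (2 * curv) / .MN_PER_M_TO_N_PER_M
  gamma[bad] <- NA_real_
  out <- data.frame(sample_id = rep_len(sample_id, n),
                    tension_mN_per_m = gamma,
                    qc_flag = ifelse(bad, "invalid_geometry", "ok"),
                    stringsAsFactors = FALSE)
  class(out) <- c("tension_estimate", "data.frame")
  out
}

#' Apply the aspiration tongue-length quality criterion
#'
#' Tension is read out when the aspirated membrane tongue reaches a target
#' length. Two published conventions are supported: tongue equal to the
#' pipette radius (`mode = "pipette_radius"`, the default) or a fixed length
#' (`mode = "fixed_length"`, default 1.5 um). A record passes when its tongue
#' is within `tolerance` (relative) of the criterion.
#'
#' @param tongue_um measured tongue length, um (NA fails the criterion).
#' @param r_pipette_um pipette radius, um (used in `pipette_radius` mode).
#' @param mode which criterion to apply.
#' @param fixed fixed criterion length, um.
#' @param tolerance relative tolerance, default 0.2.
#' @return character vector of qc flags, `"ok"` or
#'   `"tongue_criterion_not_met"`.
#' @export
apply_tongue_criterion <- function(tongue_um, r_pipette_um = NULL,
                                   mode = c("pipette_radius", "fixed_length"),
                                   fixed = 1.5, tolerance = 0.2) {
  mode <- match.arg(mode)
  if (mode == "pipette_radius") {
    if (is.null(r_pipette_um)) {
      stop("`r_pipette_um` is required in pipette_radius mode", call. = FALSE)
    }
    criterion <- r_pipette_um
  } else {
    check_positive(fixed, "fixed")
    criterion <- rep_len(fixed, length(tongue_um))
  }
  ok <- is.finite(tongue_um) & abs(tongue_um - criterion) <= tolerance * criterion
  ifelse(ok, "ok", "tongue_criterion_not_met")
}

#' Summarize tension estimates by group
#'
#' Flagged records (any `qc_flag` other than `"ok"`) are excluded. Groups in
#' which every record is flagged are reported with `n = 0` and `NA`
#' statistics rather than zeros.
#'
#' @param estimates a `tension_estimate` data frame (from
#'   [laplace_tension()]), optionally with extra columns.
#' @param group character vector of group labels, one per row; defaults to
#'   `estimates$group` if present, else a single group.
#' @return a `data.frame` with columns `group`, `n`, `mean_mN_per_m`,
#'   `sd_mN_per_m` (NA for n < 2).
#' @export
summarize_tensions <- function(estimates, group = NULL) {
  if (is.null(group)) group <- estimates$group %||% rep("all", nrow(estimates))
  stopifnot(length(group) == nrow(estimates))
  keep <- estimates$qc_flag == "ok"
  out <- do.call(rbind, lapply(split(seq_along(group), group), function(i) {
    v <- estimates$tension_mN_per_m[i][keep[i]]
    data.frame(group = group[i[1]], n = length(v),
               mean_mN_per_m = if (length(v)) mean(v) else NA_real_,
               sd_mN_per_m = if (length(v) >= 2) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read an aspiration measurement table from CSV
#'
#' Expected columns: `sample_id`, `pressure_pa`, `r_pipette_um`, `r_cell_um`,
#' optionally `tongue_um`.
#'
#' @param path CSV file path.
#' @return a `data.frame`.
#' @export
read_aspiration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "pressure_pa", "r_pipette_um", "r_cell_um")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("aspiration CSV missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Full aspiration analysis of a measurement table
#'
#' Computes Laplace tensions and, when a `tongue_um` column is present,
#' downgrades records failing the tongue criterion.
#'
#' @param measurements a `data.frame` as returned by [read_aspiration_csv()]
#'   or [generate_aspiration_table()].
#' @param tongue_mode,tolerance passed to [apply_tongue_criterion()]; set
#'   `tongue_mode = NULL` to skip the criterion.
#' @return a `tension_estimate` data frame.
#' @export
estimate_tensions <- function(measurements, tongue_mode = "pipette_radius",
                              tolerance = 0.2) {
  est <- laplace_tension(measurements$pressure_pa, measurements$r_pipette_um,
                         measurements$r_cell_um,
                         sample_id = measurements$sample_id)
  if (!is.null(tongue_mode) && "tongue_um" %in% names(measurements)) {
    tflag <- apply_tongue_criterion(measurements$tongue_um,
                                    measurements$r_pipette_um,
                                    mode = tongue_mode, tolerance = tolerance)
    demote <- est$qc_flag == "ok" & tflag != "ok"
    est$qc_flag[demote] <- tflag[demote]
  }
  est
}
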