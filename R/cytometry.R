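#' Derive gate thresholds from control samples
#'
#' Thresholds are fixed per-channel quantiles of control distributions, the
#' cytometry analogue of drawing a gate just above background:
#' * `green_thr`: quantile of the target-only control's green (CellTracker)
#'   channel — targets carry no CellTracker, so events above it are
#'   macrophages;
#' * `orange_thr`, `red_thr`: quantiles of the macrophage-only control's
#'   pHrodo and AF647 channels, which are pure background there.
#'
#' @param macrophage_only event table of the macrophage-only control.
#' @param target_only event table of the target-only control.
#' @param quantile gating quantile, default 0.995 (at most 0.5 percent of
#'   background events exceed each threshold).
#' @return an object of class `gate_thresholds`: list with `green_thr`,
#'   `orange_thr`, `red_thr`, `method`, `quantile`.
#' @export
derive_thresholds <- function(macrophage_only, target_only, quantile = 0.995) {
  if (is.null(macrophage_only) || nrow(macrophage_only) == 0) {
    stop("macrophage-only control is empty", call. = FALSE)
  }
  if (is.null(target_only) || nrow(target_only) == 0) {
    stop("target-only control is empty", call. = FALSE)
  }
  check_fraction(quantile, "quantile")
  structure(list(
    green_thr = stats::quantile(target_only$green, quantile, names = FALSE),
    orange_thr = stats::quantile(macrophage_only$orange, quantile, names = FALSE),
    red_thr = stats::quantile(macrophage_only$red, quantile, names = FALSE),
    method = "control-quantile", quantile = quantile
  ), class = "gate_thresholds")
}

#' Classify cytometry events as debris, unengaged, trogocytic, or phagocytic
#'
#' The fluorescence logic: green- events are debris (not macrophages);
#' green+/red+/orange+ events are phagocytic (antibody signal plus acidified
#' volume marker); green+/red+/orange- events are trogocytic (antibody
#' signal without volume internalization); remaining green+ events are
#' unengaged macrophages. Every event receives exactly one label. The
#' green+/orange+/red- cell of the truth table, not covered by the stated
#' rules, is labeled unengaged.
#'
#' @param events an event table with `green`, `orange`, `red` columns.
#' @param gates a `gate_thresholds` object from [derive_thresholds()].
#' @return the event table with an added `label` column (character, one of
#'   `"debris"`, `"unengaged"`, `"trogo"`, `"phago"`).
#' @export
classify_events <- function(events, gates) {
  stopifnot(inherits(gates, "gate_thresholds"))
  g <- events$green > gates$green_thr
  o <- events$orange > gates$orange_thr
  r <- events$red > gates$red_thr
  label <- rep("unengaged", nrow(events))
  label[!g] <- "debris"
  label[g & r & o] <- "phago"
  label[g & r & !o] <- "trogo"
  events$label <- label
  events
}

#' Compute trogocytic and phagocytic efficiencies from a labeled table
#'
#' Efficiencies are percentages of all CellTracker-positive (green+) events:
#' trogocytic plus phagocytic plus unengaged macrophages form the
#' denominator; debris is excluded.
#'
#' @param labeled an event table with a `label` column.
#' @return an object of class `efficiency_result`: list with
#'   `n_total_macrophage`, `n_trogo`, `n_phago`, `trogo_eff`, `phago_eff`
#'   (percent).
#' @export
compute_efficiencies <- function(labeled) {
  if (!"label" %in% names(labeled)) {
    stop("table has no `label` column; run classify_events() first",
         call. = FALSE)
  }
  n_trogo <- sum(labeled$label == "trogo")
  n_phago <- sum(labeled$label == "phago")
  n_mac <- sum(labeled$label != "debris")
  if (n_mac == 0) {
    stop("no CellTracker-positive events; efficiency undefined", call. = FALSE)
  }
  structure(list(n_total_macrophage = n_mac, n_trogo = n_trogo,
                 n_phago = n_phago,
                 trogo_eff = 100 * n_trogo / n_mac,
                 phago_eff = 100 * n_phago / n_mac),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("macrophage events: %d\n  trogocytic:  %d (%.1f%%)\n  phagocytic:  %d (%.1f%%)\n",
              x$n_total_macrophage, x$n_trogo, x$trogo_eff, x$n_phago,
              x$phago_eff))
  invisible(x)
}

#' Summarize efficiency replicates per condition
#'
#' @param results a `data.frame` with columns `condition`, `trogo_eff`,
#'   `phago_eff` (one row per replicate), or a list of `efficiency_result`
#'   objects with a parallel `condition` vector.
#' @param condition condition labels when `results` is a list.
#' @return a `data.frame` with per-condition mean and sample SD (n-1
#'   denominator; `NA` for a single replicate) of both efficiencies.
#' @export
replicate_summary <- function(results, condition = NULL) {
  if (!is.data.frame(results)) {
    condition <- condition %||% rep("all", length(results))
    results <- data.frame(
      condition = condition,
      trogo_eff = vapply(results, `[[`, numeric(1), "trogo_eff"),
      phago_eff = vapply(results, `[[`, numeric(1), "phago_eff"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(results, results$condition), function(d) {
    data.frame(condition = d$condition[1], n = nrow(d),
               trogo_mean = mean(d$trogo_eff),
               trogo_sd = if (nrow(d) >= 2) stats::sd(d$trogo_eff) else NA_real_,
               phago_mean = mean(d$phago_eff),
               phago_sd = if (nrow(d) >= 2) stats::sd(d$phago_eff) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read an event table from CSV
#'
#' Expected columns: `event_id`, `green`, `orange`, `red`, `sample`.
#'
#' @param path CSV file path.
#' @return a `data.frame`.
#' @export
read_event_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("green", "orange", "red")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("event CSV missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$green)) || any(df$green < 0) ||
      any(!is.finite(df$orange)) || any(df$orange < 0) ||
      any(!is.finite(df$red)) || any(df$red < 0)) {
    stop("channel intensities must be finite and >= 0", call. = FALSE)
  }
  df
}
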