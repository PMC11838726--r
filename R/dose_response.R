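#' Logistic dose-response fitting and critical-density extraction
#'
#' Trogocytic efficiency rises sigmoidally with antibody surface density.
#' The canonical model fitted here is the increasing logistic
#' \deqn{y = \frac{a}{1 + e^{-(x - \rho_{crit})/d}}}
#' with plateau `a` (percent, constrained to (0, 100]), inflection point
#' `rho_crit` (the critical antibody density) and width `d`. The equivalent
#' decreasing parameterization `y = a (1 - 1/(1 + e^{-(x - rho_crit)/d}))`
#' is the same curve under `d -> -d` and is available via `form`; the
#' inflection point is identical either way.
#'
#' @name dose-response
NULL

# Profiled residual sum of squares: for fixed (rho, d) the model is linear
# in the plateau a, so a is solved in closed form (clamped to (0, 100]).
.sigmoid_rss <- function(par, x, y) {
  l <- stats::plogis((x - par[1]) / exp(par[2]))
  den <- sum(l * l)
  if (den <= 0) return(sum(y^2))
  a <- min(max(sum(y * l) / den, 1e-9), 100)
  sum((y - a * l)^2)
}

.sigmoid_a_hat <- function(par, x, y) {
  l <- stats::plogis((x - par[1]) / exp(par[2]))
  min(max(sum(y * l) / sum(l * l), 1e-9), 100)
}

# Lean fitting core used by both the user-facing fit and the bootstrap:
# optimize (rho_crit, log d) with profiled plateau. `starts` is a matrix
# with columns (rho, log_d).
.fit_sigmoid_core <- function(x, y, starts, polish = TRUE) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- stats::optim(starts[i, ], .sigmoid_rss, x = x, y = y,
                        method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || res$value < best$value) best <- res
  }
  conv <- TRUE
  if (polish) {
    pol <- tryCatch(
      stats::nlminb(best$par, .sigmoid_rss, x = x, y = y,
                    control = list(rel.tol = 1e-14, abs.tol = 1e-14,
                                   iter.max = 500)),
      error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$objective) &&
        pol$objective <= best$value + 1e-12) {
      best <- list(par = pol$par, value = pol$objective)
      conv <- pol$convergence %in% c(0, 1) || pol$objective < best$value
    }
  }
  par <- unname(best$par)
  list(rho_crit = par[1], d = exp(par[2]),
       a = .sigmoid_a_hat(par, x, y), rss = best$value,
       converged = conv && is.finite(best$value) && all(is.finite(par)))
}

.sigmoid_starts <- function(x, y) {
  xr <- range(x)
  span <- diff(xr)
  if (span == 0) span <- max(abs(xr[1]), 1)
  # density where observed efficiency first crosses half its maximum
  half <- x[which.min(abs(y - max(y) / 2))]
  rho0 <- unique(c(half, stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)))
  d0 <- span * c(1 / 10, 1 / 5, 1 / 2)
  as.matrix(expand.grid(rho = rho0, log_d = log(d0)))
}

#' Fit the efficiency-vs-density sigmoid and extract the critical density
#'
#' Least-squares fit with multistart initialization (inflection candidates
#' at the observed half-maximum crossing and the density quartiles, widths
#' at 1/10, 1/5 and 1/2 of the density span), followed by a Newton-type
#' polish. The plateau is profiled out analytically, so the optimization is
#' two-dimensional and the reported optimum has RSS no larger than any
#' start.
#'
#' @param table a `data.frame` with columns `density` and `efficiency`
#'   (percent); replicate rows are pooled.
#' @param form `"increasing"` (canonical) or `"decreasing"`; the decreasing
#'   parameterization reports a sign-flipped width for the identical curve.
#' @param aggregate_replicates if `TRUE`, fit replicate means per density
#'   instead of pooled rows.
#' @return an object of class `sigmoid_fit`: list with `a`, `rho_crit`, `d`,
#'   `rss`, `converged`, `form`, `n`, and the fitted `data`.
#' @export
fit_sigmoid <- function(table, form = c("increasing", "decreasing"),
                        aggregate_replicates = FALSE) {
  form <- match.arg(form)
  if (!all(c("density", "efficiency") %in% names(table))) {
    stop("dose-response table needs `density` and `efficiency` columns",
         call. = FALSE)
  }
  if (aggregate_replicates) {
    table <- stats::aggregate(efficiency ~ density, table, mean)
  }
  x <- table$density
  y <- table$efficiency
  if (length(unique(x)) < 4) {
    stop("need at least 4 distinct densities to fit the sigmoid",
         call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("all efficiencies equal; no transition to fit", call. = FALSE)
  }
  core <- .fit_sigmoid_core(x, y, .sigmoid_starts(x, y))
  structure(list(a = core$a, rho_crit = core$rho_crit,
                 d = if (form == "decreasing") -core$d else core$d,
                 rss = core$rss, converged = core$converged, form = form,
                 n = length(x), data = table[, c("density", "efficiency")],
                 rho_crit_ci = NULL),
            class = "sigmoid_fit")
}

#' Predicted efficiency of a fitted sigmoid
#'
#' @param object a `sigmoid_fit`.
#' @param density densities at which to evaluate, antibodies/um^2.
#' @param ... unused.
#' @return numeric vector of efficiencies, percent.
#' @export
predict.sigmoid_fit <- function(object, density, ...) {
  d <- if (object$form == "decreasing") -object$d else object$d
  object$a * stats::plogis((density - object$rho_crit) / d)
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid fit (%s form): a = %.3f%%, rho_crit = %.2f /um^2, d = %.2f /um^2\n",
              x$form, x$a, x$rho_crit, x$d))
  cat(sprintf("  RSS = %.4g over %d points; converged: %s\n",
              x$rss, x$n, x$converged))
  if (!is.null(x$rho_crit_ci)) {
    cat(sprintf("  rho_crit 95%% CI: [%.2f, %.2f]\n",
                x$rho_crit_ci[1], x$rho_crit_ci[2]))
  }
  invisible(x)
}

#' Bootstrap confidence interval for the critical density
#'
#' Case-resampling bootstrap over the rows of the dose-response table: each
#' replicate resamples rows with replacement, refits the sigmoid (started
#' from the full-data optimum, with a multistart fallback on failure), and
#' the 2.5/97.5 percentiles of the refitted inflection points form the
#' interval. Deterministic under a fixed seed.
#'
#' @param table the dose-response table the fit was computed from.
#' @param fit a converged `sigmoid_fit` for `table`; computed if missing.
#' @param n_boot bootstrap draws, default 2000.
#' @param seed integer seed.
#' @return the `sigmoid_fit` with `rho_crit_ci` set (a length-2 vector with
#'   attributes `n_boot`, `prop_converged`, `reliable`). The interval is
#'   flagged unreliable when more than 20 percent of refits fail.
#' @export
bootstrap_rho_crit <- function(table, fit = NULL, n_boot = 2000, seed = 1L) {
  if (is.null(fit)) fit <- fit_sigmoid(table)
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!fit$converged) stop("cannot bootstrap a non-converged fit", call. = FALSE)
  x <- table$density
  y <- table$efficiency
  n <- length(x)
  start <- matrix(c(fit$rho_crit, log(abs(fit$d))), nrow = 1)
  fallback <- NULL
  rho <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    vapply(seq_len(n_boot), function(b) {
      xi <- x[idx[, b]]
      yi <- y[idx[, b]]
      if (length(unique(xi)) < 4 || stats::sd(yi) == 0) return(NA_real_)
      core <- .fit_sigmoid_core(xi, yi, start, polish = TRUE)
      if (!core$converged || !is.finite(core$rho_crit)) {
        if (is.null(fallback)) fallback <<- .sigmoid_starts(x, y)
        core <- .fit_sigmoid_core(xi, yi, fallback, polish = TRUE)
      }
      if (core$converged) core$rho_crit else NA_real_
    }, numeric(1))
  })
  ok <- is.finite(rho)
  ci <- stats::quantile(rho[ok], c(0.025, 0.975), names = FALSE)
  attr(ci, "n_boot") <- n_boot
  attr(ci, "prop_converged") <- mean(ok)
  attr(ci, "reliable") <- mean(ok) >= 0.8
  fit$rho_crit_ci <- ci
  fit
}

#' Linear scaling of critical density with target tension
#'
#' Fits `rho_crit = intercept + slope * tension` by OLS across conditions
#' and attaches a case-resampling bootstrap percentile band for the fitted
#' line, plus percentile intervals for slope and intercept. The mechanical
#' scaling model predicts a line through the origin with slope
#' `rho_ref / (sigma_ref * R)`.
#'
#' @param tension tensions, mN/m.
#' @param rho_crit fitted critical densities, antibodies/um^2.
#' @param n_boot bootstrap draws, default 2000.
#' @param seed integer seed.
#' @param band_at tensions at which to evaluate the confidence band;
#'   defaults to 50 points spanning the data.
#' @return list with `slope`, `intercept`, `slope_ci`, `intercept_ci`,
#'   `band` (a data.frame with `tension`, `fit`, `lower`, `upper`), `n`.
#' @export
rho_crit_vs_tension <- function(tension, rho_crit, n_boot = 2000, seed = 1L,
                                band_at = NULL) {
  stopifnot(length(tension) == length(rho_crit))
  n <- length(tension)
  if (n < 2) stop("need at least 2 (tension, rho_crit) pairs", call. = FALSE)
  fit <- stats::lm(rho_crit ~ tension)
  cf <- stats::coef(fit)
  if (is.null(band_at)) {
    band_at <- seq(min(tension), max(tension), length.out = 50)
  }
  boot <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(tension[i])) < 2) return(c(NA_real_, NA_real_))
      stats::coef(stats::lm(rho_crit[i] ~ tension[i]))
    }, numeric(2)))
  })
  ok <- stats::complete.cases(boot)
  lines <- boot[ok, 1] + outer(boot[ok, 2], band_at)   # draws x band points
  band <- data.frame(
    tension = band_at,
    fit = cf[1] + cf[2] * band_at,
    lower = apply(lines, 2, stats::quantile, 0.025, names = FALSE),
    upper = apply(lines, 2, stats::quantile, 0.975, names = FALSE))
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       slope_ci = stats::quantile(boot[ok, 2], c(0.025, 0.975), names = FALSE),
       intercept_ci = stats::quantile(boot[ok, 1], c(0.025, 0.975), names = FALSE),
       band = band, n = n)
}
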