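#' Pearson correlation with t-transform p-value
#'
#' Product-moment correlation computed from its definition, with the
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3), both with non-zero
#'   variance.
#' @return list with `r`, `n`, `t`, `p_value`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) {
    t <- Inf * sign(r); p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, n = n, t = t, p_value = p)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' F statistic from the between/within mean-square ratio; pairwise adjusted
#' p-values from the studentized-range distribution using the Tukey-Kramer
#' standard error `sqrt(MSE/2 * (1/n_i + 1/n_j))` for unbalanced groups.
#' Assumes equal within-group variance.
#'
#' @param values numeric vector of observations.
#' @param group group labels (>= 2 groups, each with >= 2 observations).
#' @return list of class `group_comparison` with `f_statistic`, `df`
#'   (between, within), `anova_p`, and `pairwise` (data.frame: `group_i`,
#'   `group_j`, `mean_diff`, `adjusted_p`).
#' @export
anova_tukey <- function(values, group) {
  stopifnot(length(values) == length(group))
  group <- as.character(group)
  sp <- split(values, group)
  k <- length(sp)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  ni <- vapply(sp, length, integer(1))
  small <- names(ni)[ni < 2]
  if (length(small)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  n <- length(values)
  means <- vapply(sp, mean, numeric(1))
  grand <- mean(values)
  ss_between <- sum(ni * (means - grand)^2)
  ss_within <- sum(vapply(sp, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- k - 1
  df2 <- n - k
  mse <- ss_within / df2
  f <- (ss_between / df1) / mse
  anova_p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  pairs <- utils::combn(names(sp), 2)
  pairwise <- data.frame(
    group_i = pairs[1, ], group_j = pairs[2, ],
    mean_diff = means[pairs[2, ]] - means[pairs[1, ]],
    adjusted_p = NA_real_, stringsAsFactors = FALSE)
  for (idx in seq_len(ncol(pairs))) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    se <- sqrt(mse / 2 * (1 / ni[[i]] + 1 / ni[[j]]))
    q <- abs(means[[j]] - means[[i]]) / se
    pairwise$adjusted_p[idx] <- if (mse == 0) {
      if (means[[i]] == means[[j]]) 1 else 0
    } else {
      stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    }
  }
  rownames(pairwise) <- NULL
  structure(list(f_statistic = f, df = c(between = df1, within = df2),
                 anova_p = anova_p, pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$f_statistic, x$anova_p))
  print(x$pairwise)
  invisible(x)
}

# Drop NULL or empty sections so the report never carries empty shells.
.compact <- function(x) {
  x[!vapply(x, function(v) is.null(v) || (is.data.frame(v) && nrow(v) == 0) ||
              (is.list(v) && length(v) == 0), logical(1))]
}

#' Assemble the final analysis report
#'
#' Collects whatever stage outputs are present into a single structured
#' document. Sections that were not produced are omitted, not emitted as
#' nulls; regeneration from identical inputs is byte-identical.
#'
#' @param sections named list; recognized names are `tensions`,
#'   `efficiencies`, `densities`, `sigmoid_fits`, `rho_crit_vs_tension`,
#'   `phase_diagram`, `correlation`, `anova`, `bite_comparison`, `meta`.
#' @return an object of class `trogo_report`: list with `sections`, `json`
#'   (string), `markdown` (string).
#' @export
build_report <- function(sections) {
  sections <- .compact(sections)
  if (length(sections) == 0) stop("no stage outputs supplied", call. = FALSE)
  ser <- lapply(sections, function(s) {
    if (inherits(s, "phase_diagram")) {
      list(regime_counts = as.list(table(s$grid$regime)),
           boundary = s$boundary, rho_min = s$rho_min)
    } else if (inherits(s, "sigmoid_fit")) {
      out <- s[c("a", "rho_crit", "d", "rss", "converged", "form")]
      if (!is.null(s$rho_crit_ci)) out$rho_crit_ci <- as.numeric(s$rho_crit_ci)
      out
    } else if (inherits(s, "group_comparison")) {
      list(f_statistic = s$f_statistic, anova_p = s$anova_p,
           pairwise = s$pairwise)
    } else s
  })
  json <- jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE, na = "null")
  md <- c("# Trogocytosis/phagocytosis analysis report", "")
  for (nm in names(ser)) {
    md <- c(md, paste0("## ", nm), "", "```json",
            as.character(jsonlite::toJSON(ser[[nm]], auto_unbox = TRUE,
                                          digits = NA, dataframe = "rows",
                                          pretty = TRUE, na = "null")),
            "```", "")
  }
  structure(list(sections = sections, json = as.character(json),
                 markdown = paste(md, collapse = "\n")),
            class = "trogo_report")
}

#' Write a report to disk
#'
#' @param report a `trogo_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (`report.json`, `report.md`).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "trogo_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("report.json", "report.md"))
  writeLines(report$json, paths[1])
  writeLines(report$markdown, paths[2])
  invisible(paths)
}
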