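#' Spearman rank correlation
#'
#' Pearson correlation of midranks (average ranks for ties).  Returns `NA`
#' with a `reason` attribute when undefined (n < 3 after removing
#' incomplete pairs, or a constant vector).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`, or `NA` with attribute `reason`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    return(structure(NA_real_, reason = "fewer than 3 complete pairs"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, reason = "constant vector"))
  stats::cor(x, y, method = "spearman")
}

#' Percentile-bootstrap confidence interval for Spearman's rho
#'
#' Resamples index pairs with replacement `B` times, recomputes the rank
#' correlation, and takes the `(1 - level)/2` and `1 - (1 - level)/2`
#' percentiles.  Replicates whose correlation is undefined (e.g. a resample
#' that is constant in one variable) are redrawn; the redraw count is
#' reported.  Deterministic given `seed`.
#'
#' @param x,y Numeric vectors, `n >= 4`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional RNG seed.
#' @return Named numeric `c(ci_low, ci_high)` with attribute `n_redrawn`.
#' @export
bootstrap_ci <- function(x, y, B = 1000, level = 0.95, seed = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4)
    stop("bootstrap_ci needs at least 4 paired observations", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  rhos <- numeric(B)
  redrawn <- 0L
  max_attempts <- 100L * B
  b <- 1L
  while (b <= B) {
    idx <- sample.int(n, n, replace = TRUE)
    r <- spearman_rho(x[idx], y[idx])
    if (is.na(r)) {
      redrawn <- redrawn + 1L
      if (redrawn > max_attempts)
        stop("bootstrap_ci: correlation undefined in almost every resample",
             call. = FALSE)
      next
    }
    rhos[b] <- r
    b <- b + 1L
  }
  qs <- stats::quantile(rhos, probs = c((1 - level) / 2,
                                        1 - (1 - level) / 2),
                        names = FALSE)
  structure(c(ci_low = qs[1], ci_high = qs[2]), n_redrawn = redrawn)
}

#' Windowed Spearman correlation between two mediators
#'
#' Pools all animals sacrificed at time points inside the window (boundary
#' times belong to every window that touches them, so 12 h contributes to
#' both a 0-12 h and a 12-48 h window; set `boundary = "right-open"` to
#' exclude the upper endpoint instead) and computes the rank correlation of
#' the two mediators with a percentile-bootstrap confidence interval.  The
#' association is called significant when the interval excludes 0.
#'
#' @param cohort A [cohort_table()].
#' @param strain,compartment Labels selecting the group.
#' @param pair Length-2 character vector of mediator names.
#' @param window Numeric `(start_h, end_h)`, canonically `c(0, 12)` or
#'   `c(12, 48)`.
#' @param B,level,seed Passed to [bootstrap_ci()].
#' @param boundary `"closed"` (default) or `"right-open"` window membership.
#' @return An object of class `spearman_ci`: list with `pair`, `window`,
#'   `strain`, `compartment`, `rho`, `ci_low`, `ci_high`, `n`, `B`,
#'   `significant`, `rho_outside_ci` (flag recording the rare percentile
#'   pathology where rho falls outside its own CI) and `n_redrawn`.
#' @export
window_correlation <- function(cohort, strain, compartment, pair,
                               window, B = 1000, level = 0.95, seed = NULL,
                               boundary = c("closed", "right-open")) {
  stopifnot(inherits(cohort, "cohort_table"), length(pair) == 2,
            length(window) == 2)
  boundary <- match.arg(boundary)
  if (pair[1] == pair[2])
    warning("self-pair requested: rank correlation is trivially 1")
  times <- unique(cohort$time_h)
  inside <- times >= window[1] &
    (if (boundary == "closed") times <= window[2] else times < window[2])
  times <- times[inside]
  a <- mediator_values(cohort, strain, compartment, pair[1], times)
  b <- mediator_values(cohort, strain, compartment, pair[2], times)
  animals <- intersect(names(a), names(b))
  x <- a[animals]; y <- b[animals]
  if (length(animals) < 4)
    stop(sprintf(
      "insufficient data: only %d animal(s) with both mediators in %g-%g h",
      length(animals), window[1], window[2]), call. = FALSE)
  rho <- spearman_rho(x, y)
  if (is.na(rho))
    stop("rank correlation undefined in window: ", attr(rho, "reason"),
         call. = FALSE)
  ci <- bootstrap_ci(x, y, B = B, level = level, seed = seed)
  structure(
    list(pair = pair, window = as.numeric(window), strain = strain,
         compartment = compartment, rho = as.numeric(rho),
         ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
         n = length(animals), B = B, level = level,
         significant = ci[["ci_low"]] > 0 || ci[["ci_high"]] < 0,
         rho_outside_ci = rho < ci[["ci_low"]] || rho > ci[["ci_high"]],
         n_redrawn = attr(ci, "n_redrawn")),
    class = "spearman_ci")
}

#' @export
print.spearman_ci <- function(x, ...) {
  cat(sprintf("Spearman correlation: %s vs %s | %s | %s | %g-%g h\n",
              x$pair[1], x$pair[2], x$strain, x$compartment,
              x$window[1], x$window[2]))
  cat(sprintf("  rho = %.3f, %g%% bootstrap CI [%.3f, %.3f], n = %d, B = %d\n",
              x$rho, 100 * x$level, x$ci_low, x$ci_high, x$n, x$B))
  cat("  significant (CI excludes 0):", x$significant, "\n")
  if (x$rho_outside_ci)
    cat("  note: rho lies outside the percentile CI\n")
  invisible(x)
}
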