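#' Planted cohort design
#'
#' Describes a synthetic cohort with known ground truth: which mediators
#' respond (deviate from their 0 h baseline mean) and which mediator pairs
#' co-vary within which time intervals.  Concentrations are generated as the
#' exponential of a multivariate normal, i.e. log-normal, because multiplex
#' immunoassay concentrations are positive and right-skewed; both responder
#' effects and planted correlations live on the log scale.
#'
#' Responder effect sizes are expressed in units of the baseline log-scale
#' standard deviation, so power statements are free of concentration units.
#' A per-strain `response_scaling` multiplies every effect for that strain
#' (e.g. 1.0 for the wild type, a fraction for a receptor-null strain).
#'
#' Planted correlations are declared per (strain, compartment, interval,
#' mediator pair).  Because animals are terminally sampled, an interval's
#' correlation is planted in the cross-section: every time point inside the
#' interval draws its animals from a multivariate normal whose correlation
#' matrix carries the planted entries, so the pooled two-endpoint sample the
#' network stage consumes shows the planted association.
#'
#' @param strains Character vector of strain labels.
#' @param compartments Character vector of compartment labels.
#' @param time_points_h Strictly increasing numeric vector starting at 0.
#' @param n_per_timepoint Named integer vector, animals per time point for
#'   each strain.
#' @param response_scaling Named numeric vector, per-strain multiplier on
#'   responder effect sizes.
#' @param responders Data frame with columns
#'   `strain, compartment, mediator, time_h, effect_sd`: the planted mean
#'   shift (in baseline-SD units, before scaling) of that mediator at that
#'   time point.  Times not listed are at baseline.
#' @param edge_blocks Data frame with columns
#'   `strain, compartment, start_h, end_h, mediator_a, mediator_b, rho`:
#'   planted log-scale correlation applied at every time point `t` with
#'   `start_h <= t <= end_h`.
#' @param noise_cv Coefficient of variation of the log-normal measurement
#'   noise (default 0.3); the log-scale SD is `sqrt(log(1 + noise_cv^2))`.
#' @param baseline_log_mean Log-scale baseline mean concentration
#'   (default `log(100)`, i.e. ~100 concentration units).
#' @param panel A [mediator_panel()].
#' @param seed Default RNG seed used by [simulate_cohort()].
#' @return An object of class `dyna_design`.
#' @seealso [simulate_cohort()], [scenario_paperlike()]
#' @export
dyna_design <- function(strains,
                        compartments,
                        time_points_h = c(0, 1, 4, 6, 12, 24, 48),
                        n_per_timepoint = stats::setNames(
                          rep(8L, length(strains)), strains),
                        response_scaling = stats::setNames(
                          rep(1, length(strains)), strains),
                        responders = empty_responders(),
                        edge_blocks = empty_edge_blocks(),
                        noise_cv = 0.3,
                        baseline_log_mean = log(100),
                        panel = mediator_panel(),
                        seed = 1L) {
  strains <- as.character(strains)
  compartments <- as.character(compartments)
  time_points_h <- as.numeric(time_points_h)
  if (length(time_points_h) < 2 || time_points_h[1] != 0 ||
      any(diff(time_points_h) <= 0))
    stop("time_points_h must be strictly increasing and start at 0",
         call. = FALSE)
  if (!all(strains %in% names(n_per_timepoint)))
    stop("n_per_timepoint must be named for every strain", call. = FALSE)
  if (!all(strains %in% names(response_scaling)))
    stop("response_scaling must be named for every strain", call. = FALSE)
  responders <- as.data.frame(responders)
  edge_blocks <- as.data.frame(edge_blocks)
  req_r <- c("strain", "compartment", "mediator", "time_h", "effect_sd")
  req_e <- c("strain", "compartment", "start_h", "end_h",
             "mediator_a", "mediator_b", "rho")
  if (!all(req_r %in% names(responders)))
    stop("responders needs columns ", paste(req_r, collapse = ", "),
         call. = FALSE)
  if (!all(req_e %in% names(edge_blocks)))
    stop("edge_blocks needs columns ", paste(req_e, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(c(responders$mediator, edge_blocks$mediator_a,
                          edge_blocks$mediator_b)), panel$names)
  if (length(bad))
    stop("design names mediator(s) outside the panel: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (nrow(edge_blocks) && any(abs(edge_blocks$rho) > 1))
    stop("planted |rho| must be <= 1", call. = FALSE)
  if (nrow(edge_blocks) && any(edge_blocks$end_h <= edge_blocks$start_h))
    stop("edge-block intervals need end_h > start_h", call. = FALSE)

  design <- structure(
    list(strains = strains, compartments = compartments,
         time_points_h = time_points_h,
         n_per_timepoint = n_per_timepoint,
         response_scaling = response_scaling,
         responders = responders, edge_blocks = edge_blocks,
         noise_cv = noise_cv, baseline_log_mean = baseline_log_mean,
         panel = panel, seed = as.integer(seed)),
    class = "dyna_design")
  # every planted correlation matrix must be a valid (PSD) correlation matrix
  for (s in strains) for (cp in compartments) for (t in time_points_h)
    planted_cor_matrix(design, s, cp, t)
  design
}

#' Planted pairs covering one analysis interval
#'
#' Returns the mediator pairs whose planted-correlation block spans the
#' whole interval `(start_h, end_h)` for one strain and compartment — the
#' ground truth an interval network should recover.
#'
#' @param design A [dyna_design()].
#' @param strain,compartment Group labels.
#' @param interval Numeric `(start_h, end_h)`.
#' @return Data frame with columns `mediator_a`, `mediator_b`, `rho`.
#' @export
planted_pairs <- function(design, strain, compartment, interval) {
  eb <- design$edge_blocks
  sel <- eb$strain == strain & eb$compartment == compartment &
    eb$start_h <= interval[1] & eb$end_h >= interval[2]
  out <- eb[sel, c("mediator_a", "mediator_b", "rho"), drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_responders <- function() {
  data.frame(strain = character(), compartment = character(),
             mediator = character(), time_h = numeric(),
             effect_sd = numeric())
}

empty_edge_blocks <- function() {
  data.frame(strain = character(), compartment = character(),
             start_h = numeric(), end_h = numeric(),
             mediator_a = character(), mediator_b = character(),
             rho = numeric())
}

# Assemble the log-scale correlation matrix active for one strain,
# compartment and time point; errors if the planted entries are not PSD.
planted_cor_matrix <- function(design, strain, compartment, time_h) {
  meds <- design$panel$names
  k <- length(meds)
  C <- diag(k)
  dimnames(C) <- list(meds, meds)
  eb <- design$edge_blocks
  sel <- eb$strain == strain & eb$compartment == compartment &
    eb$start_h <= time_h & eb$end_h >= time_h
  eb <- eb[sel, , drop = FALSE]
  if (nrow(eb)) {
    for (i in seq_len(nrow(eb))) {
      a <- eb$mediator_a[i]; b <- eb$mediator_b[i]
      if (a == b) next
      # on conflict keep the strongest planted association
      if (abs(eb$rho[i]) >= abs(C[a, b]) || C[a, b] == 0) {
        C[a, b] <- eb$rho[i]; C[b, a] <- eb$rho[i]
      }
    }
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop(sprintf(
        "design error: planted correlation matrix for (%s, %s) at %g h is not positive semi-definite",
        strain, compartment, time_h), call. = FALSE)
  }
  C
}

# Log-scale mean vector for one strain/compartment/time.
planted_mean_vector <- function(design, strain, compartment, time_h, sigma) {
  meds <- design$panel$names
  mu <- rep(design$baseline_log_mean, length(meds))
  names(mu) <- meds
  rs <- design$responders
  sel <- rs$strain == strain & rs$compartment == compartment &
    rs$time_h == time_h
  rs <- rs[sel, , drop = FALSE]
  if (nrow(rs)) {
    shift <- design$response_scaling[[strain]] * rs$effect_sd * sigma
    mu[rs$mediator] <- mu[rs$mediator] + shift
  }
  mu
}

#' Simulate a cohort from a planted design
#'
#' Draws, for every (strain, compartment, time point), `n_per_timepoint`
#' animals from a multivariate normal on the log scale whose mean carries the
#' planted responder shifts and whose correlation matrix carries the planted
#' edge blocks, then exponentiates.  All concentrations are therefore
#' strictly positive.  Animal identifiers are shared across compartments of
#' the same (strain, time point), mirroring one animal sampled in all
#' compartments at sacrifice; compartments are drawn independently.
#'
#' The draw order is fixed (strains, then compartments, then time points, in
#' design order), so a given seed always yields the same cohort.
#'
#' @param design A [dyna_design()].
#' @param seed RNG seed; defaults to the design's own seed.
#' @return An object of class `simulated_cohort`: list with elements
#'   `cohort` (a [cohort_table()]), `truth` (list with `edges` and
#'   `responders` data frames — the planted ground truth), `seed`, `design`.
#' @export
simulate_cohort <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "dyna_design"))
  sigma <- sqrt(log(1 + design$noise_cv^2))
  meds <- design$panel$names
  k <- length(meds)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)

  rows <- vector("list",
                 length(design$strains) * length(design$compartments) *
                   length(design$time_points_h))
  i <- 0L
  for (s in design$strains) {
    n <- design$n_per_timepoint[[s]]
    for (cp in design$compartments) {
      for (t in design$time_points_h) {
        C <- planted_cor_matrix(design, s, cp, t)
        mu <- planted_mean_vector(design, s, cp, t, sigma)
        draw <- MASS::mvrnorm(n, mu = mu, Sigma = sigma^2 * C)
        if (n == 1L) draw <- matrix(draw, nrow = 1L)
        conc <- exp(draw)
        i <- i + 1L
        rows[[i]] <- data.frame(
          strain = s, compartment = cp, time_h = t,
          animal_id = rep(sprintf("%s_t%g_%02d", s, t, seq_len(n)),
                          times = k),
          mediator = rep(meds, each = n),
          concentration = as.vector(conc))
      }
    }
  }
  cohort <- cohort_table(do.call(rbind, rows), design$panel)
  structure(
    list(cohort = cohort,
         truth = list(edges = design$edge_blocks,
                      responders = design$responders),
         seed = seed, design = design),
    class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated cohort (seed", x$seed, ")\n")
  cat("Planted edges:", nrow(x$truth$edges),
      "| planted responder entries:", nrow(x$truth$responders), "\n")
  print(x$cohort)
  invisible(x)
}

#' Simulate method for planted designs
#'
#' Draws `nsim` cohorts from a [dyna_design()], using seeds
#' `seed, seed + 1, ...` so replicate cohorts are independent but
#' individually reproducible.
#'
#' @param object A [dyna_design()].
#' @param nsim Number of cohorts.
#' @param seed Base seed; defaults to the design's seed.
#' @param ... Ignored.
#' @return A single `simulated_cohort` if `nsim = 1`, else a list of them.
#' @export
simulate.dyna_design <- function(object, nsim = 1, seed = object$seed, ...) {
  sims <- lapply(seq_len(nsim) - 1L,
                 function(k) simulate_cohort(object, seed = seed + k))
  if (nsim == 1) sims[[1]] else sims
}

#' @export
print.dyna_design <- function(x, ...) {
  cat("Planted cohort design\n")
  cat("  strains:     ",
      paste(sprintf("%s (n=%d/timepoint, scaling %.2g)", x$strains,
                    x$n_per_timepoint[x$strains],
                    x$response_scaling[x$strains]), collapse = "; "), "\n")
  cat("  compartments:", paste(x$compartments, collapse = ", "), "\n")
  cat("  time points: ", paste(x$time_points_h, collapse = ", "), "h\n")
  cat("  planted edge blocks:", nrow(x$edge_blocks),
      "| responder entries:", nrow(x$responders), "\n")
  cat("  noise CV:", x$noise_cv, "| seed:", x$seed, "\n")
  invisible(x)
}
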