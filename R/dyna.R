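#' Default analysis intervals
#'
#' The five consecutive time frames networks are built over:
#' 1-4, 4-6, 6-12, 12-24 and 24-48 h.  Consecutive intervals share their
#' endpoints, matching a sampling grid of 0, 1, 4, 6, 12, 24, 48 h.
#'
#' @return A two-column matrix with columns `start_h`, `end_h`.
#' @export
default_intervals <- function() {
  m <- cbind(start_h = c(1, 4, 6, 12, 24), end_h = c(4, 6, 12, 24, 48))
  m
}

validate_intervals <- function(intervals) {
  intervals <- as.matrix(intervals)
  if (ncol(intervals) != 2)
    stop("intervals must be a two-column (start_h, end_h) matrix",
         call. = FALSE)
  colnames(intervals) <- c("start_h", "end_h")
  if (any(intervals[, 2] <= intervals[, 1]))
    stop("each interval needs end_h > start_h", call. = FALSE)
  if (nrow(intervals) > 1 &&
      any(intervals[-1, 1] != intervals[-nrow(intervals), 2]))
    stop("consecutive intervals must share endpoints", call. = FALSE)
  intervals
}

interval_label <- function(interval) {
  sprintf("%g-%g h", interval[1], interval[2])
}

#' Pool the animals of one time interval into a sample matrix
#'
#' Animals are terminally sampled, so within-animal trajectories do not
#' exist; an interval's sample is the cross-section formed by pooling all
#' animals sacrificed at either endpoint of the interval.  Rows are animals,
#' columns are mediators in panel order; a missing measurement leaves an
#' `NA`, and downstream correlations use pairwise-complete rows.
#'
#' @param cohort A [cohort_table()].
#' @param strain,compartment Labels selecting the experimental group.
#' @param interval Numeric `(start_h, end_h)`.
#' @return Numeric matrix (animals x mediators) with animal ids as row
#'   names.
#' @export
interval_samples <- function(cohort, strain, compartment, interval) {
  stopifnot(inherits(cohort, "cohort_table"), length(interval) == 2)
  panel <- cohort_panel(cohort)
  sub <- cohort[cohort$strain == strain &
                  cohort$compartment == compartment &
                  cohort$time_h %in% interval, , drop = FALSE]
  for (t in interval)
    if (!any(sub$time_h == t))
      stop(sprintf(
        "no records at time point %g h for (%s, %s): cannot assemble interval %s",
        t, strain, compartment, interval_label(interval)), call. = FALSE)
  animals <- unique(sub$animal_id[order(sub$time_h, sub$animal_id)])
  m <- matrix(NA_real_, nrow = length(animals), ncol = length(panel$names),
              dimnames = list(animals, panel$names))
  m[cbind(match(sub$animal_id, animals),
          match(sub$mediator, panel$names))] <- sub$concentration
  m
}

#' Test one mediator for change from the 0 h baseline
#'
#' Compares the pooled interval values of a mediator against its 0 h control
#' values with a two-sided Mann-Whitney U (Wilcoxon rank-sum) test.  The
#' rank-based test is preferred over a t-test at the small group sizes
#' typical of terminal-sampling designs.  Exact p-values are used whenever
#' the data are tie-free; with ties the normal approximation with continuity
#' correction applies.
#'
#' @inheritParams interval_samples
#' @param mediator Panel mediator name.
#' @param alpha Significance level (default 0.05).
#' @return List with `changed` (logical, `p < alpha`), `p`, and the two
#'   group sizes `n_interval`, `n_baseline`.
#' @export
baseline_change_filter <- function(cohort, strain, compartment, interval,
                                   mediator, alpha = 0.05) {
  base <- mediator_values(cohort, strain, compartment, mediator, 0)
  vals <- mediator_values(cohort, strain, compartment, mediator, interval)
  if (length(base) == 0 && length(vals) == 0)
    # mediator not measured in this group at all: nothing to test
    return(list(changed = FALSE, p = NA_real_, n_interval = 0L,
                n_baseline = 0L))
  if (length(base) == 0)
    stop(sprintf("no baseline (0 h) group for (%s, %s)", strain,
                 compartment), call. = FALSE)
  if (length(base) < 3)
    stop(sprintf("baseline (0 h) group for (%s, %s) has fewer than 3 animals",
                 strain, compartment), call. = FALSE)
  if (length(vals) == 0)
    return(list(changed = FALSE, p = NA_real_, n_interval = 0L,
                n_baseline = length(base)))
  p <- suppressWarnings(
    stats::wilcox.test(vals, base, alternative = "two.sided")$p.value)
  list(changed = isTRUE(p < alpha), p = p,
       n_interval = length(vals), n_baseline = length(base))
}

#' Pearson correlation of one mediator pair
#'
#' Product-moment correlation on complete pairs.  Returns `NA` (with a
#' `reason` attribute) instead of erroring when the correlation is
#' undefined — fewer than 3 complete pairs, or a constant vector — so the
#' network builder can skip and log such pairs rather than propagate `NaN`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`, or `NA` with attribute `reason`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    return(structure(NA_real_, reason = "fewer than 3 complete pairs"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, reason = "constant vector"))
  stats::cor(x, y)
}

#' Build the signed correlation network of one time interval
#'
#' Implements the interval step of Dynamic Network Analysis: every mediator
#' is first tested for change from the 0 h baseline
#' ([baseline_change_filter()]); for every unordered pair of changed
#' mediators the Pearson correlation of the pooled interval sample is
#' computed, and an edge is drawn when `|r| >= threshold` (inclusive), with
#' a `+`/`-` sign from the sign of `r`.  Unchanged mediators carry no edges.
#' Node status is `unchanged`, `changed_isolated` (changed, degree 0) or
#' `changed_connected` (changed, degree >= 1).
#'
#' Pairs whose correlation is undefined (fewer than 3 complete pairs, or a
#' constant mediator) are skipped and recorded in the `skipped` element.
#'
#' @inheritParams interval_samples
#' @param threshold Inclusive absolute correlation threshold (default 0.7).
#' @param alpha Baseline-filter significance level (default 0.05).
#' @param p_adjust Multiple-testing correction applied to the baseline
#'   filter p-values across the panel (a [stats::p.adjust()] method).
#'   Default `"none"`.
#' @return An object of class `interval_network`: list with `strain`,
#'   `compartment`, `interval`, `threshold`, `alpha`, `nodes` (data frame
#'   with `mediator`, `p_baseline`, `changed`, `degree`, `change_status`),
#'   `edges` (data frame `from`, `to`, `r`, `sign`, with `from` before `to`
#'   in panel order), and `skipped` (data frame of skipped pairs and
#'   reasons).
#' @export
build_interval_network <- function(cohort, strain, compartment, interval,
                                   threshold = 0.7, alpha = 0.05,
                                   p_adjust = "none") {
  panel <- cohort_panel(cohort)
  meds <- panel$names
  samples <- interval_samples(cohort, strain, compartment, interval)

  flt <- lapply(meds, function(m)
    baseline_change_filter(cohort, strain, compartment, interval, m, alpha))
  p_raw <- vapply(flt, `[[`, 0, "p")
  p_adj <- stats::p.adjust(p_raw, method = p_adjust)
  changed <- !is.na(p_adj) & p_adj < alpha

  edges <- list()
  skipped <- list()
  idx <- which(changed)
  if (length(idx) >= 2) {
    for (ii in seq_along(idx)[-length(idx)]) {
      for (jj in seq((ii + 1), length(idx))) {
        a <- idx[ii]; b <- idx[jj]
        r <- pearson_r(samples[, a], samples[, b])
        if (is.na(r)) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            mediator_a = meds[a], mediator_b = meds[b],
            reason = attr(r, "reason"))
          next
        }
        if (abs(r) >= threshold)
          edges[[length(edges) + 1L]] <- data.frame(
            from = meds[a], to = meds[b], r = as.numeric(r),
            sign = if (r > 0) "+" else "-")
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), r = numeric(),
               sign = character())
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(mediator_a = character(), mediator_b = character(),
               reason = character())

  degree <- stats::setNames(integer(length(meds)), meds)
  if (nrow(edges)) {
    tab <- table(c(edges$from, edges$to))
    degree[names(tab)] <- as.integer(tab)
  }
  status <- ifelse(!changed, "unchanged",
                   ifelse(degree > 0, "changed_connected",
                          "changed_isolated"))
  nodes <- data.frame(mediator = meds, p_baseline = p_adj,
                      changed = changed, degree = as.integer(degree),
                      change_status = status, row.names = NULL)

  structure(
    list(strain = strain, compartment = compartment,
         interval = as.numeric(interval), threshold = threshold,
         alpha = alpha, nodes = nodes, edges = edges, skipped = skipped),
    class = "interval_network")
}

#' @export
print.interval_network <- function(x, ...) {
  cat(sprintf("Interval network: %s | %s | %s\n", x$strain, x$compartment,
              interval_label(x$interval)))
  cat(sprintf("  %d/%d mediators changed from baseline; %d edge(s) at |r| >= %g\n",
              sum(x$nodes$changed), nrow(x$nodes), nrow(x$edges),
              x$threshold))
  if (nrow(x$edges)) {
    lab <- sprintf("  %s %s %s (r = %.3f)", x$edges$from,
                   ifelse(x$edges$sign == "+", "--(+)--", "--(-)--"),
                   x$edges$to, x$edges$r)
    cat(lab, sep = "\n")
  }
  if (nrow(x$skipped))
    cat("  skipped pairs:", nrow(x$skipped), "(undefined correlation)\n")
  invisible(x)
}

#' Network complexity of an interval network
#'
#' The degree sum over all panel mediators divided by `n_mediators - 1`,
#' where `n_mediators` is the total number of mediators analysed (the panel
#' size, not the number of changed nodes).  Equals
#' `2 * n_edges / (n_mediators - 1)`.
#'
#' @param network An `interval_network`, or anything with an `edges` data
#'   frame.
#' @param n_mediators Number of mediators analysed; defaults to the
#'   network's node count.
#' @return Non-negative number.
#' @export
network_complexity <- function(network, n_mediators = nrow(network$nodes)) {
  if (is.null(n_mediators) || n_mediators < 2)
    stop("network complexity needs at least 2 mediators", call. = FALSE)
  2 * nrow(network$edges) / (n_mediators - 1)
}

#' Total connections across intervals
#'
#' Sum of edge counts over a group's interval networks.
#'
#' @param networks List of `interval_network` objects sharing one strain and
#'   compartment.
#' @return Integer edge-count total.
#' @export
total_connections <- function(networks) {
  stopifnot(length(networks) > 0,
            all(vapply(networks, inherits, TRUE, "interval_network")))
  if (length(unique(vapply(networks, `[[`, "", "strain"))) > 1 ||
      length(unique(vapply(networks, `[[`, "", "compartment"))) > 1)
    stop("total_connections requires networks of one strain and compartment",
         call. = FALSE)
  sum(vapply(networks, function(nw) nrow(nw$edges), 0L))
}

#' Ratio of connection totals between two groups
#'
#' Degenerate totals are reported in-band: `Inf` when only the denominator
#' is zero, `NaN` when both are.
#'
#' @param total_a,total_b Non-negative edge-count totals (numerator,
#'   denominator).
#' @return `total_a / total_b`, `Inf`, or `NaN`.
#' @export
connection_ratio <- function(total_a, total_b) {
  stopifnot(total_a >= 0, total_b >= 0)
  if (total_b == 0) {
    if (total_a == 0) return(NaN)
    return(Inf)
  }
  total_a / total_b
}

#' Dynamic Network Analysis of one experimental group
#'
#' Fits the full DyNA profile of one (strain, compartment): an
#' [build_interval_network()] per analysis interval, the per-interval
#' network complexity, and the total connection count.
#'
#' @inheritParams build_interval_network
#' @param intervals Two-column `(start_h, end_h)` matrix; default the five
#'   canonical intervals of [default_intervals()].
#' @return An object of class `dyna`: list with `strain`, `compartment`,
#'   `intervals`, `threshold`, `alpha`, `networks` (named list of
#'   `interval_network`), `complexity` (named numeric per interval) and
#'   `total_connections`.
#' @examples
#' sim <- simulate_cohort(scenario_paperlike(seed = 1))
#' fit <- dyna(sim$cohort, "C57BL/6", "heart")
#' fit
#' summary(fit)
#' @export
dyna <- function(cohort, strain, compartment,
                 intervals = default_intervals(), threshold = 0.7,
                 alpha = 0.05, p_adjust = "none") {
  stopifnot(inherits(cohort, "cohort_table"))
  intervals <- validate_intervals(intervals)
  if (!any(cohort$strain == strain & cohort$compartment == compartment))
    stop(sprintf("cohort has no records for (%s, %s)", strain, compartment),
         call. = FALSE)
  networks <- lapply(seq_len(nrow(intervals)), function(i)
    build_interval_network(cohort, strain, compartment, intervals[i, ],
                           threshold = threshold, alpha = alpha,
                           p_adjust = p_adjust))
  names(networks) <- apply(intervals, 1, interval_label)
  complexity <- vapply(networks, network_complexity, 0)
  structure(
    list(strain = strain, compartment = compartment, intervals = intervals,
         threshold = threshold, alpha = alpha, networks = networks,
         complexity = complexity,
         total_connections = total_connections(networks)),
    class = "dyna")
}

#' @export
print.dyna <- function(x, ...) {
  cat(sprintf("DyNA fit: %s | %s (|r| >= %g, baseline alpha = %g)\n",
              x$strain, x$compartment, x$threshold, x$alpha))
  counts <- vapply(x$networks, function(nw) nrow(nw$edges), 0L)
  cat("  interval    edges  complexity\n")
  for (i in seq_along(x$networks))
    cat(sprintf("  %-10s %5d  %10.4f\n", names(x$networks)[i], counts[i],
                x$complexity[i]))
  cat(sprintf("  total connections: %d\n", x$total_connections))
  invisible(x)
}

#' @export
summary.dyna <- function(object, ...) {
  counts <- vapply(object$networks, function(nw) nrow(nw$edges), 0L)
  changed <- vapply(object$networks, function(nw) sum(nw$nodes$changed), 0L)
  neg <- vapply(object$networks,
                function(nw) sum(nw$edges$sign == "-"), 0L)
  out <- list(
    strain = object$strain, compartment = object$compartment,
    table = data.frame(interval = names(object$networks),
                       changed_nodes = changed, edges = counts,
                       negative_edges = neg,
                       complexity = as.numeric(object$complexity),
                       row.names = NULL),
    total_connections = object$total_connections)
  class(out) <- "summary.dyna"
  out
}

#' @export
print.summary.dyna <- function(x, ...) {
  cat(sprintf("DyNA summary: %s | %s\n", x$strain, x$compartment))
  print(x$table, row.names = FALSE)
  cat("Total connections:", x$total_connections, "\n")
  invisible(x)
}

#' Plot a DyNA fit
#'
#' Draws the interval networks side by side (changed-and-connected nodes
#' red, changed-but-isolated yellow, unchanged grey; positive edges black,
#' negative red), or the complexity profile when `type = "complexity"`.
#'
#' @param x A [dyna()] fit.
#' @param type `"network"` or `"complexity"`.
#' @param ... Passed to the underlying plot calls.
#' @return `x`, invisibly.
#' @export
plot.dyna <- function(x, type = c("network", "complexity"), ...) {
  type <- match.arg(type)
  if (type == "complexity") {
    mids <- rowMeans(x$intervals)
    graphics::plot(mids, x$complexity, type = "b", pch = 16,
                   xlab = "interval midpoint (h)",
                   ylab = "network complexity",
                   main = sprintf("%s | %s", x$strain, x$compartment), ...)
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, length(x$networks)), mar = c(1, 1, 3, 1))
  on.exit(graphics::par(old))
  for (nm in names(x$networks)) {
    nw <- x$networks[[nm]]
    g <- as_igraph(nw)
    cols <- c(unchanged = "grey85", changed_isolated = "gold",
              changed_connected = "tomato")
    igraph::plot.igraph(
      g, main = nm,
      vertex.color = cols[igraph::V(g)$change_status],
      vertex.label.cex = 0.6, vertex.size = 18,
      edge.color = ifelse(igraph::E(g)$sign == "+", "black", "red"),
      layout = igraph::layout_in_circle(g), ...)
  }
  invisible(x)
}
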