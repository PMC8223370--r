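# Independent brute-force oracles, deliberately written from first
# principles rather than through the code paths they check.

# product-moment correlation straight from the covariance formula
bf_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# midranks by explicit tie-group averaging
bf_midrank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

bf_spearman <- function(x, y) bf_pearson(bf_midrank(x), bf_midrank(y))

# exact two-sided Mann-Whitney p by full enumeration of group assignments
bf_mannwhitney_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- bf_midrank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  # two-sided: assignments at least as far from the null mean as observed
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# a well-formed interval network with randomly planted edges
random_network <- function(seed, n_edges = NULL,
                           meds = default_mediators()) {
  set.seed(seed)
  k <- length(meds)
  pairs <- utils::combn(k, 2)
  if (is.null(n_edges)) n_edges <- sample(0:12, 1)
  pick <- sort(sample(ncol(pairs), n_edges))
  r <- stats::runif(n_edges, -1, 1)
  r <- ifelse(abs(r) < 0.7, sign(r) * (0.7 + 0.3 * abs(r)), r)
  edges <- data.frame(
    from = meds[pairs[1, pick]], to = meds[pairs[2, pick]],
    r = r, sign = ifelse(r > 0, "+", "-"))
  if (!n_edges) edges <- data.frame(from = character(), to = character(),
                                    r = numeric(), sign = character())
  degree <- stats::setNames(integer(k), meds)
  if (n_edges) {
    tab <- table(c(edges$from, edges$to))
    degree[names(tab)] <- as.integer(tab)
  }
  changed <- degree > 0 | stats::runif(k) < 0.3
  status <- ifelse(!changed, "unchanged",
                   ifelse(degree > 0, "changed_connected",
                          "changed_isolated"))
  nodes <- data.frame(
    mediator = meds,
    p_baseline = ifelse(changed, stats::runif(k, 0, 0.05),
                        stats::runif(k, 0.05, 1)),
    changed = changed, degree = as.integer(degree),
    change_status = status, row.names = NULL)
  structure(
    list(strain = "WT", compartment = "heart", interval = c(4, 6),
         threshold = 0.7, alpha = 0.05, nodes = nodes, edges = edges,
         skipped = data.frame(mediator_a = character(),
                              mediator_b = character(),
                              reason = character())),
    class = "interval_network")
}

# small 6-mediator panel for fast simulation-based tests
small_panel <- function() {
  mediator_panel(names = c("TNF", "IL-6", "IL-10", "KC", "MCP-1", "VEGF"))
}

# one-strain, one-compartment design with a single planted pair in the
# 4-6 h interval; all mediators respond with a flat (stationary) effect so
# the pooled cross-section carries no mean-trajectory correlation
recovery_design <- function(rho = 0.95, n = 8L, effect = 2.5, seed = 1L) {
  meds <- small_panel()$names
  responders <- expand.grid(mediator = meds, time_h = c(4, 6),
                            stringsAsFactors = FALSE)
  responders$strain <- "WT"
  responders$compartment <- "heart"
  responders$effect_sd <- effect
  eb <- data.frame(strain = "WT", compartment = "heart",
                   start_h = 4, end_h = 6,
                   mediator_a = "TNF", mediator_b = "IL-6", rho = rho)
  if (rho == 0) eb <- eb[0, , drop = FALSE]
  dyna_design(strains = "WT", compartments = "heart",
              time_points_h = c(0, 4, 6),
              n_per_timepoint = c(WT = n),
              responders = responders, edge_blocks = eb,
              panel = small_panel(), seed = seed)
}

# hand-built cohort: baseline at 0 h plus one interval's worth of data,
# values supplied per mediator as list(baseline =, t1 =, t2 =)
manual_cohort <- function(values, strain = "WT", compartment = "heart",
                          times = c(0, 4, 6), panel = small_panel()) {
  rows <- list()
  for (m in names(values)) {
    v <- values[[m]]
    stopifnot(length(v) == 3)
    for (i in 1:3) {
      vi <- v[[i]]
      if (!length(vi)) next
      rows[[length(rows) + 1L]] <- data.frame(
        strain = strain, compartment = compartment, time_h = times[i],
        animal_id = sprintf("a_t%g_%02d", times[i], seq_along(vi)),
        mediator = m, concentration = vi)
    }
  }
  cohort_table(do.call(rbind, rows), panel)
}
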