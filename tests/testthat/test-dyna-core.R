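test_that("pearson_r matches hand computation and flags degeneracy", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)),
               bf_pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)))
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  r <- pearson_r(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "constant")
  r2 <- pearson_r(c(1, 2), c(1, 2))
  expect_true(is.na(r2))
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(pearson_r(x, y), bf_pearson(x, y))
  }
})

test_that("interval samples pool the two endpoint groups", {
  sim <- simulate_cohort(recovery_design(n = 8L, seed = 5))
  m <- interval_samples(sim$cohort, "WT", "heart", c(4, 6))
  expect_equal(dim(m), c(16, 6))
  expect_identical(colnames(m), small_panel()$names)
  expect_error(interval_samples(sim$cohort, "WT", "heart", c(1, 4)),
               "no records at time point 1")
})

test_that("an animal missing one mediator is excluded only pairwise", {
  vals <- list(
    TNF = list(1:4, c(10, 11, 12, 13), c(10, 12, 14, 16)),
    `IL-6` = list(1:4, c(20, 22, 24, 26), c(21, 23, 25, 27)),
    `IL-10` = list(1:4, c(30, 31, 32, 33), c(30, 32, 34, 35)))
  cohort <- manual_cohort(vals)
  # drop IL-10 for one interval animal
  drop <- cohort$mediator == "IL-10" & cohort$animal_id == "a_t4_01"
  cohort2 <- cohort_table(as.data.frame(cohort)[!drop, ], small_panel())
  m <- interval_samples(cohort2, "WT", "heart", c(4, 6))
  expect_equal(sum(is.na(m[, "IL-10"])), 1)
  expect_true(all(!is.na(m[, "TNF"])))
  nw <- build_interval_network(cohort2, "WT", "heart", c(4, 6))
  # pairs involving IL-10 still computable on 7 complete pairs
  expect_true(all(!is.na(nw$edges$r)))
})

test_that("baseline filter matches the exact rank-permutation oracle", {
  # identical multisets cannot be called changed
  same <- list(TNF = list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(1, 2, 3, 4)))
  cohort <- manual_cohort(same)
  res <- baseline_change_filter(cohort, "WT", "heart", c(4, 6), "TNF")
  expect_false(res$changed)
  expect_gt(res$p, 0.9)

  # full separation, 8 vs 8: p equals the enumeration value 2/C(16,8)
  base <- 1:8
  high1 <- 100 + 1:4
  high2 <- 200 + 1:4
  sep <- list(TNF = list(base, high1, high2))
  cohort <- manual_cohort(sep)
  res <- baseline_change_filter(cohort, "WT", "heart", c(4, 6), "TNF")
  expect_equal(res$p, 2 / choose(16, 8))
  expect_equal(res$p, bf_mannwhitney_p(c(high1, high2), base))
  expect_true(res$changed)

  # alpha = 0 never declares change
  res0 <- baseline_change_filter(cohort, "WT", "heart", c(4, 6), "TNF",
                                 alpha = 0)
  expect_false(res0$changed)

  # random (tied) data: p agrees with the enumeration oracle when ties are
  # absent
  set.seed(42)
  for (i in 1:5) {
    x <- sample(100, 6); y <- sample(200, 5) + 0.5
    vals <- list(TNF = list(y, x[1:3], x[4:6]))
    p <- baseline_change_filter(manual_cohort(vals), "WT", "heart",
                                c(4, 6), "TNF")$p
    expect_equal(p, bf_mannwhitney_p(x, y))
  }

  expect_error(
    baseline_change_filter(
      manual_cohort(list(TNF = list(numeric(0), 1:4, 1:4))),
      "WT", "heart", c(4, 6), "TNF"),
    "no baseline")
})

test_that("networks obey the inclusive threshold and both-nodes-changed rule", {
  vals <- list(
    TNF = list(1:4, c(10, 11, 12, 13), c(14, 15, 16, 17)),
    `IL-6` = list(1:4, c(10, 12, 11, 13), c(15, 14, 17, 16)),
    `IL-10` = list(c(10, 11, 12, 13), c(10, 11, 12, 13), c(11, 12, 13, 10)))
  cohort <- manual_cohort(vals)
  m <- interval_samples(cohort, "WT", "heart", c(4, 6))
  r_obs <- pearson_r(m[, "TNF"], m[, "IL-6"])
  expect_gt(abs(r_obs), 0.7)

  nw <- build_interval_network(cohort, "WT", "heart", c(4, 6))
  # IL-10 is unchanged from baseline, so it carries no edges even though
  # it may correlate
  expect_false(nw$nodes$changed[nw$nodes$mediator == "IL-10"])
  expect_identical(nw$edges$from, "TNF")
  expect_identical(nw$edges$to, "IL-6")
  expect_identical(nw$edges$sign, "+")

  # the threshold comparison is inclusive: an edge at exactly |r| =
  # threshold stays
  nw_eq <- build_interval_network(cohort, "WT", "heart", c(4, 6),
                                  threshold = abs(r_obs))
  expect_equal(nrow(nw_eq$edges), 1)
  nw_above <- build_interval_network(
    cohort, "WT", "heart", c(4, 6),
    threshold = abs(r_obs) + 1e-12)
  expect_equal(nrow(nw_above$edges), 0)
  st <- nw_above$nodes$change_status[nw_above$nodes$mediator == "TNF"]
  expect_identical(st, "changed_isolated")
})

test_that("raising the threshold never adds edges", {
  sim <- simulate_cohort(scenario_paperlike(seed = 4))
  key <- function(e) paste(e$from, e$to)
  for (thr in list(c(0.7, 0.8), c(0.8, 0.95))) {
    lo <- build_interval_network(sim$cohort, "C57BL/6", "heart", c(4, 6),
                                 threshold = thr[1])
    hi <- build_interval_network(sim$cohort, "C57BL/6", "heart", c(4, 6),
                                 threshold = thr[2])
    expect_true(all(key(hi$edges) %in% key(lo$edges)))
  }
})

test_that("networks are invariant to positive affine per-mediator rescaling", {
  sim <- simulate_cohort(recovery_design(seed = 9))
  cohort <- sim$cohort
  nw <- build_interval_network(cohort, "WT", "heart", c(4, 6))
  scaled <- as.data.frame(cohort)
  set.seed(1)
  for (m in small_panel()$names) {
    a <- runif(1, 0.5, 3); b <- runif(1, 0, 5)
    sel <- scaled$mediator == m
    scaled$concentration[sel] <- a * scaled$concentration[sel] + b
  }
  nw2 <- build_interval_network(cohort_table(scaled, small_panel()),
                                "WT", "heart", c(4, 6))
  expect_equal(nw2$edges[c("from", "to", "sign")],
               nw$edges[c("from", "to", "sign")])
  expect_equal(nw2$nodes$change_status, nw$nodes$change_status)
  expect_equal(nw2$edges$r, nw$edges$r)
})

test_that("complexity follows the degree-sum formula", {
  nw0 <- random_network(1, n_edges = 0)
  expect_equal(network_complexity(nw0), 0)
  nw5 <- random_network(2, n_edges = 5)
  expect_equal(network_complexity(nw5), 10 / 19)
  for (seed in 1:25) {
    nw <- random_network(seed)
    expect_equal(sum(nw$nodes$degree), 2 * nrow(nw$edges))
    expect_equal(network_complexity(nw),
                 2 * nrow(nw$edges) / (nrow(nw$nodes) - 1))
  }
  expect_error(network_complexity(nw5, n_mediators = 1), "at least 2")
})

test_that("total connections sum interval edge counts", {
  counts <- c(3, 1, 0, 2, 4)
  nws <- lapply(seq_along(counts), function(i)
    random_network(i + 100, n_edges = counts[i]))
  expect_equal(total_connections(nws), 10)
  empty <- lapply(1:5, function(i) random_network(i, n_edges = 0))
  expect_equal(total_connections(empty), 0)
  # complexity identity: total = sum complexity * (n-1) / 2
  expect_equal(
    total_connections(nws),
    sum(vapply(nws, network_complexity, 0)) * 19 / 2)
  mixed <- nws
  mixed[[2]]$strain <- "KO"
  expect_error(total_connections(mixed), "one strain")
})

test_that("connection ratios use in-band degenerate markers", {
  expect_equal(connection_ratio(40, 10), 4)
  expect_identical(connection_ratio(7, 0), Inf)
  expect_identical(connection_ratio(0, 0), NaN)
})

test_that("dyna() assembles the per-interval profile", {
  sim <- simulate_cohort(scenario_paperlike(seed = 6))
  fit <- dyna(sim$cohort, "C57BL/6", "heart")
  expect_s3_class(fit, "dyna")
  expect_length(fit$networks, 5)
  expect_equal(fit$total_connections,
               sum(vapply(fit$networks, function(nw) nrow(nw$edges), 0L)))
  expect_equal(unname(fit$complexity),
               vapply(fit$networks, network_complexity, 0, USE.NAMES = FALSE))
  s <- summary(fit)
  expect_equal(sum(s$table$edges), fit$total_connections)
  expect_error(dyna(sim$cohort, "nonexistent", "heart"), "no records")
  expect_error(
    dyna(sim$cohort, "C57BL/6", "heart",
         intervals = cbind(c(1, 6), c(4, 12))),
    "share endpoints")
})

test_that("shuffling animal labels destroys planted edges", {
  hits <- 0L
  n_pairs <- 0L
  for (seed in 1:200) {
    sim <- simulate_cohort(recovery_design(rho = 0.95, seed = 300 + seed))
    m <- interval_samples(sim$cohort, "WT", "heart", c(4, 6))
    set.seed(seed)
    shuffled <- apply(m, 2, sample)
    rs <- abs(stats::cor(shuffled))
    vals <- rs[upper.tri(rs)]
    hits <- hits + sum(vals >= 0.7)
    n_pairs <- n_pairs + length(vals)
  }
  # pre-computed null envelope for |r| >= 0.7 at n = 16
  expect_lt(hits / n_pairs, 0.006)
})
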