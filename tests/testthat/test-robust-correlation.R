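test_that("spearman_rho matches the midrank oracle and rank identities", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_rho(x, exp(x)), 1.0)       # monotone transform
  expect_equal(spearman_rho(x, rev(x)), -1.0)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(3, 1, 4, 4)),
               bf_spearman(c(1, 2, 2, 4), c(3, 1, 4, 4)))
  expect_true(is.na(spearman_rho(c(2, 2, 2), c(1, 2, 3))))
  set.seed(15)
  for (i in 1:20) {
    x <- c(rnorm(8), rnorm(2)[c(1, 1)])  # with a tie
    y <- rnorm(10)
    expect_equal(spearman_rho(x, y), bf_spearman(x, y))
    # strictly monotone transforms leave rho unchanged
    expect_equal(spearman_rho(exp(x), y^3 + 2 * y), spearman_rho(x, y))
  }
})

test_that("tie-free rho equals the 1 - 6*sum(d^2)/(n(n^2-1)) closed form", {
  set.seed(16)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- sample(1000, n); y <- sample(1000, n)
    d <- rank(x) - rank(y)
    expect_equal(spearman_rho(x, y), 1 - 6 * sum(d^2) / (n * (n^2 - 1)))
  }
})

test_that("bootstrap CIs are deterministic and degenerate correctly", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  y <- c(2, 7, 1, 8, 2.8, 1.8, 2.9)
  ci1 <- bootstrap_ci(x, y, B = 500, seed = 7)
  ci2 <- bootstrap_ci(x, y, B = 500, seed = 7)
  expect_identical(ci1, ci2)
  expect_lte(ci1[["ci_low"]], ci1[["ci_high"]])
  # y == x: every resample has rho 1
  ci <- bootstrap_ci(1:10, 1:10, B = 200, seed = 1)
  expect_equal(unname(ci), c(1, 1), ignore_attr = TRUE)
  expect_error(bootstrap_ci(1:3, 1:3), "at least 4")
})

test_that("bootstrap CI width shrinks with sample size", {
  widths <- function(n, reps = 25) {
    vapply(seq_len(reps), function(i) {
      set.seed(1000 + i + n)
      x <- rnorm(n); y <- 0.5 * x + rnorm(n, sd = sqrt(0.75))
      ci <- bootstrap_ci(x, y, B = 300, seed = i)
      ci[["ci_high"]] - ci[["ci_low"]]
    }, 0)
  }
  expect_lt(median(widths(40)), median(widths(10)))
})

test_that("window pooling honours the shared 12 h boundary", {
  times <- c(0, 1, 4, 6, 12, 24, 48)
  rows <- do.call(rbind, lapply(times, function(t) {
    ids <- sprintf("m_t%g_%d", t, 1:4)
    rbind(
      data.frame(strain = "WT", compartment = "plasma", time_h = t,
                 animal_id = ids, mediator = "TNF",
                 concentration = runif(4, 1, 100)),
      data.frame(strain = "WT", compartment = "plasma", time_h = t,
                 animal_id = ids, mediator = "IL-6",
                 concentration = runif(4, 1, 100)))
  }))
  set.seed(17)
  panel <- mediator_panel(names = c("TNF", "IL-6"))
  cohort <- cohort_table(rows, panel)
  early <- window_correlation(cohort, "WT", "plasma", c("TNF", "IL-6"),
                              c(0, 12), B = 100, seed = 2)
  late <- window_correlation(cohort, "WT", "plasma", c("TNF", "IL-6"),
                             c(12, 48), B = 100, seed = 2)
  expect_equal(early$n, 20)  # 0,1,4,6,12 h: 12 h included
  expect_equal(late$n, 12)   # 12,24,48 h: 12 h in both windows
  open <- window_correlation(cohort, "WT", "plasma", c("TNF", "IL-6"),
                             c(0, 12), B = 100, seed = 2,
                             boundary = "right-open")
  expect_equal(open$n, 16)
  expect_warning(
    window_correlation(cohort, "WT", "plasma", c("TNF", "TNF"), c(0, 12),
                       B = 50, seed = 1),
    "self-pair")
  expect_error(
    window_correlation(cohort, "WT", "liver", c("TNF", "IL-6"), c(0, 12),
                       B = 50),
    "insufficient data")
})

test_that("a planted late-window association is detected only late", {
  d <- scenario_paperlike(seed = 8)
  sim <- simulate_cohort(d)
  late <- window_correlation(sim$cohort, "C57BL/6", "spleen",
                             c("IL-17A", "GM-CSF"), c(12, 48), B = 500,
                             seed = 3)
  early <- window_correlation(sim$cohort, "C57BL/6", "spleen",
                              c("IL-17A", "GM-CSF"), c(0, 12), B = 500,
                              seed = 3)
  expect_true(late$significant)
  expect_gt(late$rho, 0)
  expect_false(early$significant)
  ko_late <- window_correlation(sim$cohort, "TLR4-null", "spleen",
                                c("IL-17A", "GM-CSF"), c(12, 48), B = 500,
                                seed = 3)
  expect_false(ko_late$significant)
})
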