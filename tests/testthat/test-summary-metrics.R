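constant_cohort <- function(level = 1, strain = "WT",
                            times = c(0, 1, 4, 6, 12, 24, 48), n = 3) {
  rows <- do.call(rbind, lapply(times, function(t) data.frame(
    strain = strain, compartment = "heart", time_h = t,
    animal_id = sprintf("%s_t%g_%02d", strain, t, 1:n),
    mediator = "TNF", concentration = level)))
  cohort_table(rows, small_panel())
}

test_that("trapezoidal AUC reproduces rectangle and triangle areas", {
  expect_equal(mediator_auc(constant_cohort(1), "WT", "heart", "TNF"), 48)
  tri <- data.frame(
    strain = "WT", compartment = "heart", time_h = rep(c(0, 24, 48), 2),
    animal_id = paste0("m", 1:6), mediator = "TNF",
    concentration = c(0, 10, 0, 0, 10, 0))
  expect_equal(
    mediator_auc(cohort_table(tri, small_panel()), "WT", "heart", "TNF"),
    240)
})

test_that("AUC equals fine-grid integration of the mean trajectory", {
  set.seed(13)
  times <- c(0, 1, 4, 6, 12, 24, 48)
  means <- runif(length(times), 5, 50)
  rows <- do.call(rbind, lapply(seq_along(times), function(i) data.frame(
    strain = "WT", compartment = "heart", time_h = times[i],
    animal_id = sprintf("m_t%g_%d", times[i], 1:4), mediator = "TNF",
    concentration = means[i] + c(-1, 1, -2, 2))))  # mean is means[i]
  cohort <- cohort_table(rows, small_panel())
  grid <- sort(unique(c(seq(0, 48, length.out = 20001), times)))
  interp <- stats::approx(times, means, xout = grid)$y
  oracle <- sum((interp[-1] + interp[-length(grid)]) / 2 * diff(grid))
  expect_equal(mediator_auc(cohort, "WT", "heart", "TNF"), oracle,
               tolerance = 1e-9)
})

test_that("AUC is additive over abutting ranges and scales linearly", {
  set.seed(14)
  times <- c(0, 1, 4, 6, 12, 24, 48)
  rows <- do.call(rbind, lapply(times, function(t) data.frame(
    strain = "WT", compartment = "heart", time_h = t,
    animal_id = sprintf("m_t%g_%d", t, 1:3), mediator = "TNF",
    concentration = runif(3, 1, 100))))
  cohort <- cohort_table(rows, small_panel())
  full <- mediator_auc(cohort, "WT", "heart", "TNF", 0, 48)
  expect_equal(full,
               mediator_auc(cohort, "WT", "heart", "TNF", 0, 24) +
                 mediator_auc(cohort, "WT", "heart", "TNF", 24, 48))
  scaled <- transform(as.data.frame(cohort), concentration = concentration * 3)
  expect_equal(mediator_auc(cohort_table(scaled, small_panel()),
                            "WT", "heart", "TNF"), 3 * full)
})

test_that("single-time-point AUCs are refused", {
  one <- data.frame(strain = "WT", compartment = "heart", time_h = 0,
                    animal_id = "m1", mediator = "TNF", concentration = 5)
  expect_error(mediator_auc(cohort_table(one, small_panel()),
                            "WT", "heart", "TNF"), "one time point")
})

test_that("identical strains give an AUC ratio of exactly 1", {
  sim <- simulate_cohort(recovery_design(seed = 31))
  a <- as.data.frame(sim$cohort)
  b <- a
  b$strain <- "KO"
  b$animal_id <- paste0("KO_", b$animal_id)
  both <- cohort_table(rbind(a, b), small_panel())
  s <- compartment_auc_summary(both, "heart", strains = c("WT", "KO"))
  expect_equal(s$strain_ratio, 1.0)
  expect_equal(unname(s$compartment_sum[1]), sum(s$per_mediator[, 1]))
  # common rescaling of both strains leaves the ratio invariant
  doubled <- transform(rbind(a, b), concentration = concentration * 2)
  s2 <- compartment_auc_summary(cohort_table(doubled, small_panel()),
                                "heart", strains = c("WT", "KO"))
  expect_equal(s2$strain_ratio, 1.0)
  expect_equal(s2$compartment_sum, 2 * s$compartment_sum)
  expect_error(compartment_auc_summary(both, "heart",
                                       strains = c("WT", "missing")),
               "absent")
})

test_that("a suppressed responder strain yields a ratio far above 1", {
  d <- recovery_design(effect = 3, seed = 41)
  strong <- simulate_cohort(d)
  flat <- recovery_design(effect = 0, seed = 42)
  weak <- simulate_cohort(flat)
  b <- as.data.frame(weak$cohort)
  b$strain <- "KO"
  b$animal_id <- paste0("KO_", b$animal_id)
  both <- cohort_table(rbind(as.data.frame(strong$cohort), b),
                       small_panel())
  s <- compartment_auc_summary(both, "heart", strains = c("WT", "KO"))
  expect_gt(s$strain_ratio, 1.3)
})
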