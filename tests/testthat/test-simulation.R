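test_that("criterion staircases follow the increment and reversal rules", {
  expect_equal(build_criteria(4), c(15, 20, 25, 30))
  expect_equal(build_criteria(4, reversal = TRUE), c(15, 20, 15, 25))
  expect_equal(build_criteria(6, baseline_level = 0, increment = 2),
               c(2, 4, 6, 8, 10, 12))
  expect_equal(build_criteria(5, increment = 0), rep(10, 5))
  expect_error(build_criteria(3, reversal = TRUE), "at least 4")
})

test_that("phase-length patterns are deterministic and respect the minimum of 3", {
  expect_equal(build_phase_lengths(4, 16, "uniform"), rep(4L, 4))
  expect_equal(build_phase_lengths(4, 20, "increasing"), c(3L, 5L, 6L, 6L))
  expect_equal(build_phase_lengths(5, 19, "triangular"), c(3L, 4L, 5L, 4L, 3L))
  expect_error(build_phase_lengths(4, 18, "uniform"), "divide")
  expect_error(build_phase_lengths(4, 11, "increasing"), "at least 3")

  for (I in 3:7) for (m in seq(3 * I, 3 * I + 12)) {
    for (pat in c("increasing", "triangular")) {
      lens <- build_phase_lengths(I, m, pat)
      expect_identical(sum(lens), as.integer(m))
      expect_true(all(lens >= 3L))
      if (pat == "increasing") expect_true(all(diff(lens) >= 0L))
      else expect_true(lens[1] == 3L && lens[I] == 3L)
    }
  }
})

test_that("AR(1) noise is stationary with unit marginal variance", {
  set.seed(8)
  z0 <- generate_ar1(1e5, 0)
  expect_equal(stats::var(z0), 1, tolerance = 0.02)
  zp <- generate_ar1(1e5, 0.3)
  expect_equal(stats::var(zp), 1, tolerance = 0.02)
  expect_equal(unname(stats::acf(zp, plot = FALSE)$acf[2]), 0.3,
               tolerance = 0.02)
  zn <- generate_ar1(1e5, -0.3)
  expect_equal(stats::var(zn), 1, tolerance = 0.02)
  expect_equal(unname(stats::acf(zn, plot = FALSE)$acf[2]), -0.3,
               tolerance = 0.02)
  expect_error(generate_ar1(10, 1), "inside")
})

test_that("effect series track the criterion with criterion-proportional noise", {
  cond0 <- simulation_condition("PCM", I = 4, lengths = c(3, 3, 3, 3),
                                variability = 0)
  expect_equal(generate_effect_series(cond0)$scores,
               rep(c(15, 20, 25, 30), each = 3))

  cond <- simulation_condition("PCM", I = 4, lengths = c(3, 3, 3, 3),
                               variability = 0.10, phi = 0)
  set.seed(21)
  draws <- replicate(4000, generate_effect_series(cond)$scores)
  crit_occ <- rep(c(15, 20, 25, 30), each = 3)
  expect_equal(rowMeans(draws), crit_occ, tolerance = 0.01)
  expect_equal(apply(draws, 1, stats::sd), 0.10 * crit_occ,
               tolerance = 0.03)
})

test_that("null series sit at the length-weighted mean criterion level", {
  cond <- simulation_condition("BAC", I = 4, lengths = rep(3, 4),
                               baseline_level = 0, increment = 5,
                               variability = 0, effect = FALSE)
  # criteria 5, 10, 15, 20 with equal lengths: level 12.5
  expect_equal(generate_null_series(cond)$scores, rep(12.5, 12))

  cond <- simulation_condition("PCM", I = 2, lengths = c(3, 1),
                               baseline_level = 10, increment = 5,
                               variability = 0, effect = FALSE,
                               pcm_k_min = 1)
  # criteria 15, 20 weighted 3:1 -> 16.25
  expect_equal(generate_null_series(cond)$scores, rep(16.25, 4))
})

test_that("zero variability with an effect gives power 1", {
  cond <- simulation_condition("PCM", I = 4, m = 15, lengths = "increasing",
                               variability = 0, phi = 0, replications = 20)
  expect_equal(estimate_rejection_rate(cond, seed = 1)$rejection_rate, 1)
  cond <- simulation_condition("BAC", I = 10, m = 30, variability = 0,
                               replications = 20)
  expect_equal(estimate_rejection_rate(cond, seed = 1)$rejection_rate, 1)
})

test_that("rejection-rate estimates are reproducible and carry binomial standard errors", {
  cond <- simulation_condition("BAC", I = 10, m = 30, variability = 0.25,
                               phi = 0, replications = 100)
  a <- estimate_rejection_rate(cond, seed = 12)
  b <- estimate_rejection_rate(cond, seed = 12)
  expect_identical(a$rejection_rate, b$rejection_rate)
  r <- a$rejection_rate
  expect_equal(a$mc_se, sqrt(r * (1 - r) / 100))
})

test_that("condition grids echo the factors and are seed-deterministic", {
  conds <- list(
    simulation_condition("BAC", I = 10, m = 30, variability = 0.25,
                         replications = 50),
    simulation_condition("PCM", I = 4, m = 16, lengths = "uniform",
                         variability = 0.25, effect = FALSE,
                         replications = 50))
  g1 <- run_condition_grid(conds, seed = 4)
  g2 <- run_condition_grid(conds, seed = 4)
  expect_identical(g1, g2)
  expect_identical(nrow(g1), 2L)
  expect_equal(g1$procedure, c("BAC", "PCM"))
  expect_equal(g1$m, c(30L, 16L))
  expect_true(all(g1$rate >= 0 & g1$rate <= 1))
  expect_error(run_condition_grid(list(conds[[1]], "x")), "2")
})

test_that("invalid conditions are rejected up front", {
  expect_error(simulation_condition("BAC", I = 9, m = 27), "even")
  expect_error(simulation_condition("PCM", I = 4, m = 10), "infeasible")
  expect_error(simulation_condition("PCM", I = 3, m = 12, reversal = TRUE),
               "at least 4")
  expect_error(simulation_condition("BAC", I = 10, m = 30,
                                    lengths = "random"), "PCM only")
  expect_error(simulation_condition("PCM", I = 4, lengths = c(3, 3, 3)),
               "one entry per phase")
})

test_that("power is nonincreasing in variability (PCM and BAC)", {
  rates <- function(proc, ...) {
    vapply(c(0.10, 0.25, 0.50), function(v)
      estimate_rejection_rate(
        simulation_condition(proc, ..., variability = v, phi = 0,
                             replications = 400), seed = 55)$rejection_rate,
      numeric(1))
  }
  slack <- 2 * sqrt(0.25 / 400)   # 2 * worst-case binomial MC se
  expect_true(all(diff(rates("BAC", I = 10, m = 30)) <= slack))
  expect_true(all(diff(rates("PCM", I = 4, m = 16,
                             lengths = "uniform")) <= slack))
})

test_that("a mini-reversal increases PCM power on matched conditions", {
  p <- function(rev) estimate_rejection_rate(
    simulation_condition("PCM", I = 5, m = 20, lengths = "uniform",
                         variability = 0.25, phi = 0, reversal = rev,
                         replications = 600), seed = 9)$rejection_rate
  expect_gt(p(TRUE), p(FALSE))
})
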