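test_that("composition counts match the closed form when the maximum is non-binding", {
  for (I in 2:5) for (k in 1:4) for (m in (I * k):(I * k + 8)) {
    expect_equal(count_randomizations(pcm_design(m, I, k)),
                 choose(m - I * k + I - 1, I - 1))
  }
})

test_that("counts with a binding maximum match brute force", {
  cases <- list(c(15, 4, 3, 6), c(19, 5, 3, 7), c(20, 4, 2, 5),
                c(12, 3, 1, 7), c(16, 4, 4, 4))
  for (cs in cases) {
    expect_equal(
      count_randomizations(pcm_design(cs[1], cs[2], cs[3], cs[4])),
      nrow(brute_force_compositions(cs[1], cs[2], cs[3], cs[4])))
  }
})

test_that("infeasible designs are rejected", {
  expect_error(pcm_design(10, 4, 3), "infeasible")
  expect_error(pcm_design(30, 4, 3, 5), "infeasible")
  expect_error(pcm_design(12, 1, 3), "at least 2 phases")
  expect_error(pcm_design(12, 4, 5, 3), "k_min exceeds k_max")
})

test_that("enumeration is exact, unique and lexicographic", {
  e <- enumerate_compositions(pcm_design(15, 4, 3, 6))
  expect_identical(nrow(e), 20L)
  expect_equal(e[1, ], c(3L, 3L, 3L, 6L))
  expect_equal(e[20, ], c(6L, 3L, 3L, 3L))
  expect_same_rows(e, brute_force_compositions(15, 4, 3, 6))

  expect_equal(enumerate_compositions(pcm_design(6, 2, 3)),
               matrix(c(3L, 3L), 1))

  # random small designs against the brute-force oracle
  set.seed(1)
  for (rep in 1:25) {
    I <- sample(2:4, 1); k <- sample(1:3, 1)
    m <- sample((I * k):18, 1)
    kmax <- sample(k:(m - (I - 1) * k), 1)
    if (m > I * kmax) next
    e <- enumerate_compositions(pcm_design(m, I, k, kmax))
    expect_same_rows(e, brute_force_compositions(m, I, k, kmax))
  }
})

test_that("enumeration above the cap directs to Monte Carlo mode", {
  expect_error(enumerate_compositions(pcm_design(40, 8, 3), cap = 1000),
               "Monte Carlo")
})

test_that("sampled compositions are admissible and cover a forced design", {
  des <- pcm_design(12, 4, 3)          # single admissible composition
  expect_true(all(sample_compositions(des, 5) == 3L))

  set.seed(99)
  des <- pcm_design(19, 5, 3, 7)
  draws <- sample_compositions(des, 500)
  expect_true(all(rowSums(draws) == 19L))
  expect_true(all(draws >= 3L & draws <= 7L))
})

test_that("the PCM test returns p = 1 under complete ties and 1/R for a unique minimum", {
  # constant scores, all criteria equal: every composition ties
  ser <- intervention_series(rep(5, 12), c(3, 3, 3, 3), rep(5, 4))
  expect_equal(pcm_test(ser, k_min = 3)$p, 1)

  # scores equal to their criteria under the actual composition only
  lens <- c(3, 4, 4, 4)
  crit <- c(15, 20, 25, 30)
  ser <- intervention_series(rep(crit, times = lens), lens, crit)
  res <- pcm_test(ser, k_min = 3, k_max = 6)
  expect_identical(res$n_randomizations, 20)
  expect_equal(res$p, 1 / 20)
  expect_equal(res$observed, min(res$reference))
  expect_identical(sum(res$reference <= res$observed), 1L)
})

test_that("the PCM test rejects inadmissible observed assignments", {
  ser <- intervention_series(rnorm(12), c(2, 4, 3, 3), c(1, 2, 3, 4))
  expect_error(pcm_test(ser, k_min = 3), "admissible")
})

test_that("Monte Carlo mode includes the observed assignment in the reference", {
  lens <- c(3, 4, 4, 4)
  crit <- c(15, 20, 25, 30)
  ser <- intervention_series(rep(crit, times = lens), lens, crit)
  set.seed(5)
  res <- pcm_test(ser, k_min = 3, k_max = 6, mode = "monte_carlo",
                  samples = 200)
  expect_length(res$reference, 201)
  expect_gte(res$p, 1 / 201)
  # p has the (1 + #{sampled <= observed}) / (samples + 1) form
  expect_equal(res$p * 201, round(res$p * 201))
  expect_equal(res$observed, min(res$reference))
})

test_that("reference MADs computed segment-wise agree with the direct statistic", {
  set.seed(11)
  des <- pcm_design(18, 4, 3, 9)
  comps <- enumerate_compositions(des)
  y <- rnorm(18, 20, 5)
  crit <- c(12, 18, 24, 30)
  ref <- ccdrand:::pcm_reference_mads(y, crit, comps)
  direct <- apply(comps, 1, function(l) mad_statistic(y, l, crit))
  expect_equal(ref, direct)
})

test_that("the PCM test is exact when data are independent of the assignment", {
  # flat data around a fixed level; actual composition drawn uniformly
  set.seed(2026)
  des <- pcm_design(20, 4, 3)
  crit <- build_criteria(4)
  reps <- 2000
  lens <- sample_compositions(des, reps)
  hits <- 0L
  for (r in seq_len(reps)) {
    y <- mean(crit) + 0.25 * mean(crit) * generate_ar1(20, 0)
    p <- pcm_test(intervention_series(y, lens[r, ], crit), k_min = 3)$p
    hits <- hits + (p <= 0.05)
  }
  expect_lte(hits / reps, 0.065)
})
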