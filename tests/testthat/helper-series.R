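# Shared fixture builders; everything is generated in code.

# Ten-phase staircase with distinct criteria inside every block; scores
# equal to the phase criteria, so the observed assignment is the unique
# MAD minimiser among all within-block orders (and, for PCM, among all
# compositions whenever boundaries shift onto a different level).
matched_series <- function(I = 10, phase_length = 3, increment = 5) {
  crit <- build_criteria(I, baseline_level = 10, increment = increment)
  intervention_series(rep(crit, each = phase_length),
                      rep(phase_length, I), crit)
}

# The 49-occasion layout of the worked example: 12 baseline occasions
# followed by 37 intervention measurements in 10 phases (lengths read off
# the actual phase-change occasions 19, 22, ..., 43).
ann_layout_series <- function() {
  lens <- c(6, 3, 3, 3, 3, 3, 3, 3, 3, 7)
  crit <- c(1, 2, 3, 4, 3, 5, 6, 7, 6, 8)
  ccd_series(phase = rep(c("base", paste0("P", 1:10)), c(12, lens)),
             session = 1:49,
             scores = c(rep(0.5, 12), rep(crit, times = lens)) +
               0.1 * sin(1:49),
             criterion = c(rep(NA, 12), rep(crit, times = lens)))
}

# Brute-force composition oracle: every bounded length tuple, filtered on
# the total. Independent of the package's DP/recursive code paths.
brute_force_compositions <- function(m, I, k_min, k_max) {
  g <- as.matrix(expand.grid(rep(list(seq.int(k_min, k_max)), I)))[, I:1,
                                                                   drop = FALSE]
  g <- g[rowSums(g) == m, , drop = FALSE]
  g[do.call(order, as.data.frame(g)), , drop = FALSE]
}

expect_same_rows <- function(a, b) {
  expect_equal(unname(a), unname(b))
}
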