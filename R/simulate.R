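#' Criterion levels for a simulated changing criterion design
#'
#' Builds the staircase of criterion levels used by the data generator:
#' starting one increment above the baseline level, each phase's criterion
#' is one increment above the previous. With `reversal = TRUE` the
#' penultimate phase steps back down one increment (a mini-reversal to a
#' previous, less stringent criterion) and the last phase resumes the
#' staircase one increment above the level before the reversal.
#'
#' @param I number of intervention phases (at least 2; at least 4 with a
#'   reversal).
#' @param baseline_level level of the (unmodelled) baseline; default 10.
#' @param increment criterion step between successive phases, in outcome
#'   units; default 5.
#' @param reversal insert a mini-reversal in the penultimate phase?
#' @return Numeric vector of `I` criterion levels.
#' @export
#' @examples
#' build_criteria(4)                          # 15 20 25 30
#' build_criteria(4, reversal = TRUE)         # 15 20 15 25
build_criteria <- function(I, baseline_level = 10, increment = 5,
                           reversal = FALSE) {
  I <- as.integer(I)
  if (I < 2L) stop("at least 2 intervention phases are required")
  crit <- baseline_level + seq_len(I) * increment
  if (reversal) {
    if (I < 4L)
      stop("a mini-reversal requires at least 4 intervention phases")
    crit[I - 1L] <- crit[I - 2L] - increment
    crit[I] <- crit[I - 2L] + increment
  }
  crit
}

#' Deterministic phase-length patterns
#'
#' Builds the vector of actual phase lengths for a simulated series
#' according to one of three patterns, each deterministic: `uniform` (all
#' phases equal; requires `I` to divide `m`), `increasing` (first phase at
#' the minimum of 3, the surplus above `3 * I` spread over the later
#' phases as evenly as possible with remainders going to the latest
#' phases, giving a nondecreasing vector), and `triangular` (both end
#' phases held at 3, the surplus assigned round-robin to interior phases
#' ordered by proximity to the middle, earlier phase first on ties).
#'
#' @param I number of phases.
#' @param m total series length; must be at least `3 * I`.
#' @param pattern `"uniform"`, `"increasing"` or `"triangular"`.
#' @return Integer vector of `I` phase lengths summing to `m`, all at
#'   least 3.
#' @export
#' @examples
#' build_phase_lengths(4, 16, "uniform")      # 4 4 4 4
#' build_phase_lengths(4, 20, "increasing")   # 3 5 6 6
#' build_phase_lengths(5, 19, "triangular")   # 3 4 5 4 3
build_phase_lengths <- function(I, m,
                                pattern = c("uniform", "increasing",
                                            "triangular")) {
  pattern <- match.arg(pattern)
  I <- as.integer(I); m <- as.integer(m)
  if (m < 3L * I)
    stop("series length ", m, " cannot give ", I,
         " phases of at least 3 measurements")
  if (pattern == "uniform") {
    if (m %% I != 0L)
      stop("uniform pattern requires the number of phases to divide ",
           "the series length")
    return(rep.int(m %/% I, I))
  }
  q <- m - 3L * I
  lens <- rep.int(3L, I)
  if (q == 0L) return(lens)
  if (pattern == "increasing") {
    add <- q %/% (I - 1L)
    rem <- q %% (I - 1L)
    lens[-1L] <- lens[-1L] + add
    if (rem > 0L)
      lens[seq.int(I - rem + 1L, I)] <- lens[seq.int(I - rem + 1L, I)] + 1L
  } else {                                  # triangular
    if (I < 3L)
      stop("triangular pattern needs at least 3 phases to have an interior")
    interior <- seq.int(2L, I - 1L)
    ord <- interior[order(abs(interior - (I + 1) / 2), interior)]
    k <- length(ord)
    lens[ord] <- lens[ord] + q %/% k
    rem <- q %% k
    if (rem > 0L) lens[ord[seq_len(rem)]] <- lens[ord[seq_len(rem)]] + 1L
  }
  lens
}

#' Stationary AR(1) noise with unit marginal variance
#'
#' Generates a first-order autoregressive Gaussian sequence
#' `z[t] = phi * z[t-1] + u[t]` with innovations scaled to
#' `Var(u) = 1 - phi^2`, so the marginal (stationary) variance is 1 for
#' every `phi`. The first value is drawn from the stationary distribution.
#' Scaling the innovations this way keeps the marginal noise level
#' comparable across autocorrelation conditions, so that power differences
#' across `phi` reflect dependence, not inflated variance.
#'
#' @param n sequence length.
#' @param phi lag-1 autocorrelation, strictly inside (-1, 1).
#' @return Numeric vector of length `n`.
#' @export
generate_ar1 <- function(n, phi = 0) {
  if (abs(phi) >= 1) stop("phi must lie strictly inside (-1, 1)")
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1")
  u <- stats::rnorm(n)
  if (phi == 0) return(u)
  u[-1L] <- u[-1L] * sqrt(1 - phi^2)
  as.numeric(stats::filter(u, phi, method = "recursive"))
}

#' One cell of the simulation grid
#'
#' Bundles everything needed to generate data and run one randomization
#' test repeatedly: the procedure, the design shape, the data-generating
#' parameters, and the test settings. Actual phase lengths for PCM can be
#' fixed (an explicit vector or a deterministic pattern, see
#' [build_phase_lengths()]) or drawn uniformly from the admissible
#' composition set anew in every replicate (`lengths = "random"`). BAC
#' phase lengths are always fixed; the actual within-block criterion order
#' is drawn by a fair coin per block in every replicate.
#'
#' @param procedure `"PCM"` or `"BAC"`.
#' @param I number of intervention phases.
#' @param m total number of intervention measurements. Required unless
#'   `lengths` is an explicit vector.
#' @param lengths either an explicit integer vector of `I` phase lengths,
#'   a pattern name (`"uniform"`, `"increasing"`, `"triangular"`), or
#'   `"random"` (PCM only: the actual composition is re-drawn uniformly
#'   per replicate). Default: `"uniform"` for BAC, `"random"` for PCM.
#' @param baseline_level,increment,reversal see [build_criteria()].
#' @param variability noise scale as a proportion of the local level
#'   (criterion level in effect conditions, overall mean level in
#'   no-effect conditions); the paper-typical grid is .10, .25, .50.
#' @param phi lag-1 autocorrelation of the noise; see [generate_ar1()].
#' @param effect `TRUE` to generate criterion-tracking data (power),
#'   `FALSE` for flat no-effect data (type I error).
#' @param replications Monte Carlo replications per condition.
#' @param alpha nominal significance level.
#' @param pcm_k_min minimum phase length defining the PCM reference set.
#' @param pcm_mode `"systematic"` (enumerate all compositions) or
#'   `"monte_carlo"`; see [pcm_test()].
#' @param mc_samples Monte Carlo sample size when `pcm_mode` is
#'   `"monte_carlo"`.
#' @return An object of class `simulation_condition`.
#' @export
simulation_condition <- function(procedure = c("PCM", "BAC"), I, m = NULL,
                                 lengths = NULL, baseline_level = 10,
                                 increment = 5, variability = 0.25,
                                 phi = 0, effect = TRUE, reversal = FALSE,
                                 replications = 1000L, alpha = 0.05,
                                 pcm_k_min = 3L,
                                 pcm_mode = c("systematic", "monte_carlo"),
                                 mc_samples = 1000L) {
  procedure <- match.arg(procedure)
  pcm_mode <- match.arg(pcm_mode)
  I <- as.integer(I)
  if (reversal && I < 4L)
    stop("a mini-reversal requires at least 4 intervention phases")
  if (is.null(lengths))
    lengths <- if (procedure == "BAC") "uniform" else "random"
  if (is.character(lengths)) {
    lengths <- match.arg(lengths,
                         c("random", "uniform", "increasing", "triangular"))
    if (is.null(m))
      stop("m is required when lengths are given as a pattern")
    m <- as.integer(m)
    if (lengths == "random") {
      if (procedure == "BAC")
        stop("BAC phase lengths are fixed; 'random' lengths apply to PCM only")
      phase_lengths <- NULL
    } else {
      phase_lengths <- build_phase_lengths(I, m, lengths)
    }
  } else {
    phase_lengths <- as.integer(lengths)
    if (length(phase_lengths) != I)
      stop("explicit lengths must have one entry per phase")
    m <- sum(phase_lengths)
    lengths <- "explicit"
  }
  if (procedure == "PCM") {
    design <- pcm_design(m, I, pcm_k_min)   # validates feasibility
    if (!is.null(phase_lengths) &&
        (any(phase_lengths < design$k_min) || any(phase_lengths > design$k_max)))
      stop("actual phase lengths are not admissible under the PCM design")
  } else if (I %% 2L != 0L) {
    stop("BAC requires an even number of phases")
  }
  if (variability < 0) stop("variability must be nonnegative")
  structure(list(procedure = procedure, I = I, m = m,
                 lengths = lengths, phase_lengths = phase_lengths,
                 baseline_level = baseline_level, increment = increment,
                 variability = variability, phi = phi, effect = effect,
                 reversal = reversal,
                 replications = as.integer(replications), alpha = alpha,
                 pcm_k_min = as.integer(pcm_k_min), pcm_mode = pcm_mode,
                 mc_samples = as.integer(mc_samples)),
            class = "simulation_condition")
}

#' @export
print.simulation_condition <- function(x, ...) {
  cat(x$procedure, " condition: I = ", x$I, ", m = ", x$m,
      ", lengths = ", x$lengths,
      ", variability = ", x$variability, ", phi = ", x$phi,
      ", ", if (x$effect) "effect" else "no effect",
      if (x$reversal) ", reversal" else "",
      ", ", x$replications, " replications\n", sep = "")
  invisible(x)
}

# Resolve the actual phase lengths of one replicate.
actual_lengths <- function(condition, design = NULL) {
  if (!is.null(condition$phase_lengths)) return(condition$phase_lengths)
  drop(sample_compositions(design, 1L))
}

# Criterion-tracking scores: y_t = c(t) + variability * c(t) * z_t, with
# one AR(1) stream spanning the whole series (dependence is not reset at
# phase changes) and the noise scale following the local criterion.
gen_effect_scores <- function(crit_occ, variability, phi) {
  crit_occ + variability * crit_occ * generate_ar1(length(crit_occ), phi)
}

# Flat no-effect scores around the length-weighted mean criterion level,
# with constant noise scale variability * L.
gen_null_scores <- function(lengths, crit, variability, phi) {
  m <- sum(lengths)
  L <- sum(lengths * crit) / m
  L + variability * L * generate_ar1(m, phi)
}

#' Generate one series under the intervention-effect model
#'
#' Scores track the phase criterion: `y[t] = c(t) + s(t) * z[t]`, where
#' `c(t)` is the criterion of the phase containing occasion `t`, `z` is a
#' unit-variance stationary AR(1) stream over the whole series, and the
#' noise scale `s(t) = variability * c(t)` is proportional to the local
#' criterion (larger criteria carry proportionally larger variability).
#'
#' @param condition a [simulation_condition()] with `effect = TRUE`.
#' @return An [intervention_series()] whose phase lengths are the
#'   condition's actual lengths (drawn uniformly from the admissible set
#'   if the condition uses random lengths).
#' @export
generate_effect_series <- function(condition) {
  stopifnot(inherits(condition, "simulation_condition"))
  if (!condition$effect) stop("condition has effect = FALSE")
  design <- if (condition$procedure == "PCM")
    pcm_design(condition$m, condition$I, condition$pcm_k_min) else NULL
  lens <- actual_lengths(condition, design)
  crit <- build_criteria(condition$I, condition$baseline_level,
                         condition$increment, condition$reversal)
  y <- gen_effect_scores(rep(crit, times = lens), condition$variability,
                         condition$phi)
  intervention_series(y, lens, crit)
}

#' Generate one series under the no-effect model
#'
#' Scores are flat: there is no shift between phases. The level is the
#' length-weighted average of the criterion levels (the simple average
#' when all phases are equally long), and the noise scale is constant at
#' `variability` times that level. The criterion labels are retained so
#' the randomization test can be applied to the mismatching flat data,
#' which is how type I error is probed.
#'
#' @param condition a [simulation_condition()] with `effect = FALSE`.
#' @return An [intervention_series()].
#' @export
generate_null_series <- function(condition) {
  stopifnot(inherits(condition, "simulation_condition"))
  if (condition$effect) stop("condition has effect = TRUE")
  design <- if (condition$procedure == "PCM")
    pcm_design(condition$m, condition$I, condition$pcm_k_min) else NULL
  lens <- actual_lengths(condition, design)
  crit <- build_criteria(condition$I, condition$baseline_level,
                         condition$increment, condition$reversal)
  y <- gen_null_scores(lens, crit, condition$variability, condition$phi)
  intervention_series(y, lens, crit)
}

#' Estimate the rejection rate of one simulation condition
#'
#' Runs `replications` independent generate-and-test cycles. In each
#' replicate the actual assignment is drawn at random from the admissible
#' set (PCM with random lengths: a uniform composition; BAC: a fair coin
#' per block deciding the within-block criterion order; PCM with a fixed
#' pattern: the pattern vector itself), the data are generated under that
#' actual assignment, the randomization test is applied, and rejections at
#' `alpha` are tallied. With `effect = TRUE` the rate estimates power;
#' with `effect = FALSE` it estimates the type I error rate.
#'
#' @param condition a [simulation_condition()].
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `ccd_sim_estimate`: a list with the
#'   condition, `rejection_rate`, its binomial Monte Carlo standard error
#'   `mc_se = sqrt(r * (1 - r) / replications)`, and `replications`.
#' @export
estimate_rejection_rate <- function(condition, seed = NULL) {
  stopifnot(inherits(condition, "simulation_condition"))
  if (!is.null(seed)) set.seed(seed)
  reps <- condition$replications
  crit <- build_criteria(condition$I, condition$baseline_level,
                         condition$increment, condition$reversal)
  rejected <- logical(reps)

  if (condition$procedure == "BAC") {
    lens <- condition$phase_lengths
    m <- condition$m
    B <- condition$I %/% 2L
    orders <- enumerate_orders(make_blocks(
      intervention_series(numeric(m), lens, crit)))
    occ <- orders[, rep(seq_len(condition$I), times = lens), drop = FALSE]
    R <- nrow(occ)
    for (r in seq_len(reps)) {
      bits <- stats::rbinom(B, 1L, 0.5)
      idx <- 1L + sum(bits * 2L^(seq_len(B) - 1L))
      y <- if (condition$effect)
        gen_effect_scores(occ[idx, ], condition$variability, condition$phi)
      else
        gen_null_scores(lens, orders[idx, ], condition$variability,
                        condition$phi)
      ref <- rowMeans(abs(occ - rep(y, each = R)))
      p <- sum(ref <= ref[idx]) / R
      rejected[r] <- p <= condition$alpha
    }
  } else {
    design <- pcm_design(condition$m, condition$I, condition$pcm_k_min)
    systematic <- condition$pcm_mode == "systematic"
    comps <- if (systematic) enumerate_compositions(design) else NULL
    for (r in seq_len(reps)) {
      lens <- actual_lengths(condition, design)
      y <- if (condition$effect)
        gen_effect_scores(rep(crit, times = lens), condition$variability,
                          condition$phi)
      else
        gen_null_scores(lens, crit, condition$variability, condition$phi)
      obs <- pcm_reference_mads(y, crit, lens)
      if (systematic) {
        ref <- pcm_reference_mads(y, crit, comps)
        p <- sum(ref <= obs) / length(ref)
      } else {
        sampled <- pcm_reference_mads(
          y, crit, sample_compositions(design, condition$mc_samples))
        p <- (1 + sum(sampled <= obs)) / (condition$mc_samples + 1)
      }
      rejected[r] <- p <= condition$alpha
    }
  }
  rate <- mean(rejected)
  structure(list(condition = condition, rejection_rate = rate,
                 mc_se = sqrt(rate * (1 - rate) / reps),
                 replications = reps),
            class = "ccd_sim_estimate")
}

#' @export
print.ccd_sim_estimate <- function(x, ...) {
  cat(if (x$condition$effect) "Power" else "Type I error",
      sprintf("estimate: %.3f (MC se %.3f, %d replications)\n",
              x$rejection_rate, x$mc_se, x$replications))
  invisible(x)
}

#' Run a grid of simulation conditions
#'
#' Estimates the rejection rate of every condition and collects the
#' results in a long-format table. Each condition gets its own
#' reproducible RNG substream derived from the master seed and its index
#' in the grid by a fixed counter scheme
#' (`(seed + 7919 * index) mod (2^31 - 1)`), so the output is identical
#' for the same master seed and grid, and any single condition can be
#' rerun on its own with the same result.
#'
#' @param conditions a list of [simulation_condition()] objects.
#' @param seed master integer seed.
#' @return A data.frame with one row per condition: the condition factors
#'   (`procedure`, `I`, `m`, `lengths`, `variability`, `phi`, `increment`,
#'   `effect`, `reversal`, `replications`) plus `rate` and `mc_se`.
#' @export
run_condition_grid <- function(conditions, seed = 1L) {
  if (inherits(conditions, "simulation_condition"))
    conditions <- list(conditions)
  bad <- which(!vapply(conditions, inherits, logical(1),
                       "simulation_condition"))
  if (length(bad))
    stop("conditions ", paste(bad, collapse = ", "),
         " are not simulation_condition objects")
  rows <- lapply(seq_along(conditions), function(i) {
    cond <- conditions[[i]]
    est <- estimate_rejection_rate(
      cond, seed = (seed + 7919 * i) %% 2147483647)
    data.frame(procedure = cond$procedure, I = cond$I, m = cond$m,
               lengths = cond$lengths, variability = cond$variability,
               phi = cond$phi, increment = cond$increment,
               effect = cond$effect, reversal = cond$reversal,
               replications = cond$replications,
               rate = est$rejection_rate, mc_se = est$mc_se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
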