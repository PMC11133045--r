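#' Phase-change-moment randomization design
#'
#' Describes the admissible set of a phase-change-moment (PCM)
#' randomization: all ways of dividing `m` intervention measurements into
#' `I` consecutive phases whose lengths lie between `k_min` and `k_max`.
#' Each admissible division is a bounded integer composition of `m` into
#' `I` parts; the criterion levels stay attached to the phase ranks (first
#' criterion to first segment, and so on), only the change moments are
#' randomized.
#'
#' @param m total number of intervention measurements.
#' @param I number of intervention phases (at least 2).
#' @param k_min minimum phase length (default 3, the conventional floor
#'   for criterion phases).
#' @param k_max maximum phase length; defaults to `m - (I - 1) * k_min`,
#'   the largest length any phase can have when all others are at the
#'   minimum (a non-binding bound).
#' @return An object of class `pcm_design`.
#' @seealso [count_randomizations()], [enumerate_compositions()],
#'   [sample_compositions()], [pcm_test()]
#' @export
#' @examples
#' pcm_design(m = 37, I = 10, k_min = 3)
pcm_design <- function(m, I, k_min = 3L, k_max = NULL) {
  m <- as.integer(m); I <- as.integer(I); k_min <- as.integer(k_min)
  if (I < 2L) stop("at least 2 phases are required")
  if (k_min < 1L) stop("k_min must be positive")
  if (is.null(k_max)) {
    k_max <- m - (I - 1L) * k_min     # implicit, non-binding maximum
  } else {
    k_max <- as.integer(k_max)
    if (k_min > k_max) stop("k_min exceeds k_max")
  }
  if (m < I * k_min || m > I * k_max)
    stop("infeasible design: no composition of ", m, " into ", I,
         " parts in [", k_min, ", ", k_max, "]")
  structure(list(m = m, I = I, k_min = k_min, k_max = k_max),
            class = "pcm_design")
}

#' @export
print.pcm_design <- function(x, ...) {
  cat("PCM design: ", x$m, " measurements, ", x$I, " phases, lengths in [",
      x$k_min, ", ", x$k_max, "]; ", format(count_randomizations(x),
      big.mark = ","), " randomizations\n", sep = "")
  invisible(x)
}

# Dynamic-programming count table: (I+1) x (m+1) matrix with
# N[j+1, s+1] = number of compositions of s into j parts in [k_min, k_max].
# Counts are stored as doubles (exact up to 2^53).
composition_count_table <- function(design) {
  m <- design$m; I <- design$I
  N <- matrix(0, nrow = I + 1L, ncol = m + 1L)
  N[1L, 1L] <- 1
  for (j in seq_len(I)) {
    for (s in seq.int(j * design$k_min, min(m, j * design$k_max))) {
      lo <- max(design$k_min, s - (j - 1L) * design$k_max)
      hi <- min(design$k_max, s - (j - 1L) * design$k_min)
      if (lo <= hi)
        N[j + 1L, s + 1L] <- sum(N[j, (s - hi):(s - lo) + 1L])
    }
  }
  N
}

#' Count the admissible randomizations of a design
#'
#' For a PCM design, the exact number of compositions of `m` into `I`
#' parts each within the length bounds, computed by dynamic programming;
#' when the maximum length is non-binding this equals the closed form
#' `choose(m - I * k_min + I - 1, I - 1)`. For a BAC design, `2^B` where
#' `B` is the number of blocks.
#'
#' @param design a [pcm_design()] or a BAC design from [make_blocks()].
#' @return The exact count, as a double.
#' @export
#' @examples
#' count_randomizations(pcm_design(37, 10, 3))  # 11440
count_randomizations <- function(design) UseMethod("count_randomizations")

#' @export
count_randomizations.pcm_design <- function(design) {
  N <- composition_count_table(design)
  N[design$I + 1L, design$m + 1L]
}

#' Enumerate all admissible phase-length compositions
#'
#' Lists every composition of `m` into `I` parts within the design's
#' length bounds, exactly once, in lexicographic order (first phase
#' varying slowest). Systematic listing is refused above `cap`
#' compositions; use Monte Carlo sampling ([sample_compositions()])
#' instead for such designs.
#'
#' @param design a [pcm_design()].
#' @param cap refuse to enumerate more than this many compositions
#'   (default `1e6`).
#' @return An integer matrix with one row per composition and `I` columns.
#' @export
#' @examples
#' enumerate_compositions(pcm_design(15, 4, 3, 6))  # 20 rows
enumerate_compositions <- function(design, cap = 1e6) {
  stopifnot(inherits(design, "pcm_design"))
  R <- count_randomizations(design)
  if (R > cap)
    stop("design has ", format(R, big.mark = ","), " randomizations, above ",
         "the enumeration cap (", format(cap, big.mark = ","),
         "); use Monte Carlo mode")
  I <- design$I
  out <- matrix(0L, nrow = R, ncol = I)
  row <- 0L
  part <- integer(I)
  recurse <- function(pos, s) {
    j <- I - pos        # parts remaining after this one
    if (j == 0L) {
      part[I] <<- s
      row <<- row + 1L
      out[row, ] <<- part
      return(invisible())
    }
    lo <- max(design$k_min, s - j * design$k_max)
    hi <- min(design$k_max, s - j * design$k_min)
    for (l in seq.int(lo, hi)) {
      part[pos] <<- l
      recurse(pos + 1L, s - l)
    }
  }
  recurse(1L, design$m)
  out
}

#' Sample phase-length compositions uniformly
#'
#' Draws compositions uniformly at random from the admissible set of a
#' PCM design by sequential conditional sampling: the length of each
#' successive phase is drawn with probability proportional to the number
#' of ways the remaining phases can complete the series. This is exact
#' uniform sampling (no rejection step), so it works even when feasible
#' compositions are a vanishing fraction of all bounded length tuples.
#'
#' @param design a [pcm_design()].
#' @param n number of compositions to draw (i.i.d., with replacement).
#' @return An integer matrix with `n` rows and `I` columns; every row sums
#'   to `m` and respects the length bounds.
#' @export
sample_compositions <- function(design, n = 1L) {
  stopifnot(inherits(design, "pcm_design"))
  n <- as.integer(n)
  N <- composition_count_table(design)
  I <- design$I
  lens <- design$k_min:design$k_max
  L <- length(lens)
  out <- matrix(0L, nrow = n, ncol = I)
  s <- rep.int(design$m, n)              # remaining sum per draw
  for (pos in seq_len(I - 1L)) {
    j <- I - pos                         # parts remaining after this one
    # weight matrix: completions of (s - l) into j parts
    rest <- outer(s, lens, "-")          # n x L
    W <- matrix(0, nrow = n, ncol = L)
    ok <- rest >= j * design$k_min & rest <= j * design$k_max
    W[ok] <- N[j + 1L, rest[ok] + 1L]
    cw <- W %*% upper.tri(diag(L), diag = TRUE)  # row-wise cumulative sums
    u <- stats::runif(n) * cw[, L]
    pick <- 1L + as.integer(rowSums(cw < u))
    out[, pos] <- lens[pick]
    s <- s - lens[pick]
  }
  out[, I] <- s
  out
}

# Reference MAD values for a set of compositions, via per-criterion
# cumulative sums of |score - level|: the MAD of a composition is a sum of
# segment totals read off the cumulative arrays, O(I) per composition.
# The observed statistic is computed through this same path so that ties
# in the randomization distribution are exact.
pcm_reference_mads <- function(scores, criterion_levels, comps) {
  m <- length(scores)
  I <- length(criterion_levels)
  A <- matrix(0, nrow = I, ncol = m + 1L)
  for (i in seq_len(I))
    A[i, -1L] <- cumsum(abs(scores - criterion_levels[i]))
  if (is.null(dim(comps))) comps <- matrix(comps, nrow = 1L)
  bounds <- comps %*% upper.tri(diag(I), diag = TRUE)  # cumulative lengths
  bounds <- cbind(0L, bounds)
  ref <- numeric(nrow(comps))
  for (i in seq_len(I))
    ref <- ref + (A[i, bounds[, i + 1L] + 1L] - A[i, bounds[, i] + 1L])
  ref / m
}

#' Phase-change-moment randomization test
#'
#' Tests whether the measurements track the criterion levels more closely
#' under the phase lengths actually used than under the other admissible
#' phase-change moments. The criterion order is fixed; the reference
#' distribution is the MAD statistic recomputed for every admissible
#' composition of phase lengths (systematic mode) or for a uniform Monte
#' Carlo sample of compositions (Monte Carlo mode). The p-value is the
#' lower-tail proportion of reference statistics at or below the observed
#' one; in Monte Carlo mode the observed assignment is included in the
#' reference set, giving `p = (1 + #\{sampled MAD <= observed\}) /
#' (samples + 1)`, which keeps the test valid.
#'
#' @param series an [intervention_series()] (baseline already removed, see
#'   [strip_baseline()]). Its observed `phase_lengths` must themselves be
#'   admissible under the length bounds.
#' @param k_min,k_max phase-length bounds defining the admissible set; see
#'   [pcm_design()].
#' @param mode `"systematic"` (all compositions; the default) or
#'   `"monte_carlo"`.
#' @param samples Monte Carlo sample size (default 1000).
#' @param cap enumeration cap for systematic mode.
#' @return A `ccd_randomization_result` with elements `observed`
#'   (the observed MAD), `reference` (the randomization distribution),
#'   `p`, `mode` and `n_randomizations` (size of the admissible set).
#' @export
#' @examples
#' set.seed(1)
#' y <- rep(c(15, 20, 25, 30), times = c(4, 5, 5, 6)) + rnorm(20)
#' ser <- intervention_series(y, c(4, 5, 5, 6), c(15, 20, 25, 30))
#' pcm_test(ser, k_min = 3)
pcm_test <- function(series, k_min = 3L, k_max = NULL,
                     mode = c("systematic", "monte_carlo"),
                     samples = 1000L, cap = 1e6) {
  stopifnot(inherits(series, "intervention_series"))
  mode <- match.arg(mode)
  design <- pcm_design(m = length(series$scores),
                       I = length(series$phase_lengths),
                       k_min = k_min, k_max = k_max)
  if (any(series$phase_lengths < design$k_min) ||
      any(series$phase_lengths > design$k_max))
    stop("observed phase lengths fall outside [", design$k_min, ", ",
         design$k_max, "]; the observed assignment must be admissible")
  R <- count_randomizations(design)
  observed <- pcm_reference_mads(series$scores, series$criterion_levels,
                                 series$phase_lengths)
  if (mode == "systematic") {
    comps <- enumerate_compositions(design, cap = cap)
    reference <- pcm_reference_mads(series$scores, series$criterion_levels,
                                    comps)
    p <- randomization_pvalue(observed, reference)
  } else {
    comps <- sample_compositions(design, n = samples)
    sampled <- pcm_reference_mads(series$scores, series$criterion_levels,
                                  comps)
    reference <- c(observed, sampled)
    p <- (1 + sum(sampled <= observed)) / (samples + 1)
  }
  randomization_result("PCM", observed, reference, p, mode, R)
}
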