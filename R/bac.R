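#' Blocked-alternating-criterion randomization design
#'
#' Pairs the intervention phases of a series into consecutive blocks of
#' two. Under blocked-alternating-criterion (BAC) randomization the phase
#' boundaries are fixed and the order of the two criterion levels within
#' each block is random, giving `2^B` admissible assignments for `B`
#' blocks. The observed criterion order is recorded as the actual
#' randomization.
#'
#' @param series an [intervention_series()] with an even number of phases.
#' @return An object of class `bac_design` with elements `B` (number of
#'   blocks), `phase_lengths` (fixed, attached to phase positions) and
#'   `criterion_levels` (the observed order).
#' @seealso [enumerate_orders()], [bac_test()]
#' @export
#' @examples
#' ser <- intervention_series(rep(c(5, 10), each = 3), c(3, 3), c(5, 10))
#' make_blocks(ser)
make_blocks <- function(series) {
  stopifnot(inherits(series, "intervention_series"))
  I <- length(series$phase_lengths)
  if (I %% 2L != 0L)
    stop("BAC requires an even number of intervention phases (got ", I,
         "); blocks of two cannot be formed")
  structure(list(B = I %/% 2L,
                 phase_lengths = series$phase_lengths,
                 criterion_levels = series$criterion_levels),
            class = "bac_design")
}

#' @export
print.bac_design <- function(x, ...) {
  cat("BAC design: ", x$B, " blocks of two phases; 2^", x$B, " = ",
      2^x$B, " randomizations\n", sep = "")
  invisible(x)
}

#' @export
count_randomizations.bac_design <- function(design) 2^design$B

#' Enumerate all within-block criterion orders
#'
#' Lists the `2^B` criterion-level vectors obtained by independently
#' keeping or swapping the two criterion levels within each block. Phase
#' lengths remain attached to phase positions; only the levels move. Rows
#' follow binary counting with block 1 as the least significant bit
#' (bit 0 = observed order, bit 1 = swapped), so row 1 is the observed
#' assignment.
#'
#' @param design a [bac_design][make_blocks()].
#' @return A numeric matrix with `2^B` rows and one column per phase.
#' @export
enumerate_orders <- function(design) {
  stopifnot(inherits(design, "bac_design"))
  B <- design$B
  crit <- design$criterion_levels
  R <- 2L^B
  out <- matrix(0, nrow = R, ncol = 2L * B)
  for (r in seq_len(R)) {
    bits <- bitwAnd(bitwShiftR(r - 1L, seq_len(B) - 1L), 1L)
    lv <- crit
    for (b in which(bits == 1L)) {
      i <- 2L * b - 1L
      lv[c(i, i + 1L)] <- lv[c(i + 1L, i)]
    }
    out[r, ] <- lv
  }
  out
}

#' Blocked-alternating-criterion randomization test
#'
#' Tests whether the measurements track the criterion levels more closely
#' under the criterion order actually used than under the other
#' within-block orders. The reference distribution is always systematic:
#' the MAD statistic is recomputed for all `2^B` orders, and the p-value
#' is the lower-tail proportion of reference statistics at or below the
#' observed one. With fewer than five blocks the smallest attainable
#' p-value exceeds .05, so a warning is issued below ten phases.
#'
#' @param series an [intervention_series()] with an even number of phases
#'   (baseline already removed, see [strip_baseline()]).
#' @return A `ccd_randomization_result`; see [pcm_test()] for the fields.
#' @export
#' @examples
#' crit <- rep(c(15, 20, 25, 30, 35), each = 2) + c(0, 5)
#' ser <- intervention_series(rep(crit, each = 3), rep(3, 10), crit)
#' bac_test(ser)  # scores equal criteria: p = 1/32
bac_test <- function(series) {
  design <- make_blocks(series)
  if (design$B < 5L)
    warning("with ", design$B, " block(s) the smallest attainable p-value is ",
            format(2^-design$B, digits = 3),
            "; at least 5 blocks (10 phases) are needed to reject at .05")
  orders <- enumerate_orders(design)
  # expand each order to one criterion value per occasion
  occ <- orders[, rep(seq_along(design$phase_lengths),
                      times = design$phase_lengths), drop = FALSE]
  reference <- rowMeans(abs(occ - rep(series$scores, each = nrow(occ))))
  observed <- reference[1L]   # row 1 is the observed order
  p <- randomization_pvalue(observed, reference)
  randomization_result("BAC", observed, reference, p,
                       "systematic", 2^design$B)
}
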