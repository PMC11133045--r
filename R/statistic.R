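#' Mean absolute deviation of scores from their phase criteria
#'
#' The test statistic shared by both randomization procedures: the mean,
#' over all m intervention measurements, of the absolute distance between
#' each measurement and the criterion level of the phase it falls in under
#' a given assignment of phase lengths and criterion levels. A small value
#' indicates close tracking of the criterion. Each occasion is weighted
#' equally, so phases contribute in proportion to their length.
#'
#' @param scores numeric vector of intervention measurements.
#' @param phase_lengths positive integers summing to `length(scores)`.
#' @param criterion_levels numeric criterion per phase, same length as
#'   `phase_lengths`.
#' @return A single nonnegative number.
#' @export
#' @examples
#' mad_statistic(c(12, 14, 19, 21), c(2, 2), c(13, 20))  # 1
mad_statistic <- function(scores, phase_lengths, criterion_levels) {
  if (length(phase_lengths) != length(criterion_levels))
    stop("phase_lengths and criterion_levels must have equal length")
  if (sum(phase_lengths) != length(scores))
    stop("phase lengths sum to ", sum(phase_lengths),
         " but there are ", length(scores), " scores")
  mean(abs(scores - rep(criterion_levels, times = phase_lengths)))
}

#' One-sided randomization p-value
#'
#' Lower-tail p-value of a randomization test: the proportion of reference
#' statistics as small as or smaller than the observed one. Under
#' systematic enumeration the reference distribution contains the observed
#' assignment's statistic, so the p-value is at least `1/length(reference)`.
#' Ties are resolved by exact `<=` comparison on the computed values;
#' reference statistics should therefore be computed by the same code path
#' as the observed one.
#'
#' @param observed observed value of the test statistic.
#' @param reference numeric vector: the randomization distribution.
#' @return p-value in (0, 1].
#' @export
randomization_pvalue <- function(observed, reference) {
  if (length(reference) == 0L)
    stop("reference distribution is empty")
  if (is.na(observed) || anyNA(reference))
    stop("missing values in test statistics")
  sum(reference <= observed) / length(reference)
}

# Internal constructor for test results shared by pcm_test() and bac_test().
randomization_result <- function(procedure, observed, reference, p,
                                 mode, n_randomizations) {
  structure(list(procedure = procedure, observed = observed,
                 reference = reference, p = p, mode = mode,
                 n_randomizations = n_randomizations),
            class = "ccd_randomization_result")
}

#' @export
print.ccd_randomization_result <- function(x, ...) {
  cat(x$procedure, "randomization test\n")
  cat("  reference distribution: ", length(x$reference), " statistics (",
      if (x$mode == "systematic")
        paste0("systematic, all ", format(x$n_randomizations,
                                          scientific = FALSE),
               " randomizations")
      else paste0("Monte Carlo sample of ",
                  format(x$n_randomizations, scientific = FALSE),
                  " randomizations"),
      ")\n", sep = "")
  cat(sprintf("  observed MAD: %.4f\n", x$observed))
  cat(sprintf("  p-value: %.6g (rounded: %.2f)\n", x$p, round(x$p, 2)))
  invisible(x)
}

#' Plot the randomization distribution of a test result
#'
#' Histogram of the reference distribution of MAD values with the observed
#' statistic marked by a vertical line.
#'
#' @param x a result from [pcm_test()] or [bac_test()].
#' @param ... passed on to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.ccd_randomization_result <- function(x, ...) {
  graphics::hist(x$reference, main = paste(x$procedure, "randomization distribution"),
                 xlab = "MAD", ...)
  graphics::abline(v = x$observed, col = "red", lwd = 2)
  invisible(x)
}
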