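#' One-way eta-squared of a simulation factor
#'
#' Proportion of the total variance in a response (here, rejection-rate
#' estimates over a simulation grid) attributable to one factor:
#' `SS_between / SS_total` from a one-way ANOVA decomposition. Benchmarks
#' commonly used for this scale: .01-.05 small, .06-.14 medium, .15-1
#' large. A constant response returns 0.
#'
#' @param grid data.frame holding the response and factor columns (e.g.
#'   the output of [run_condition_grid()]).
#' @param factor name of the grouping column; coerced to a factor.
#' @param response name of the numeric response column (default
#'   `"rate"`).
#' @return Eta-squared in \[0, 1\].
#' @export
#' @examples
#' g <- data.frame(rate = c(1, 2, 3, 4), f = c("A", "A", "B", "B"))
#' eta_squared_oneway(g, "f")  # 0.8
eta_squared_oneway <- function(grid, factor, response = "rate") {
  y <- grid[[response]]
  g <- as.factor(grid[[factor]])
  if (nlevels(droplevels(g)) < 2L)
    stop("factor '", factor, "' needs at least 2 observed levels")
  ss_total <- sum((y - mean(y))^2)
  if (ss_total == 0) return(0)
  # between-groups SS from the fitted one-way decomposition; no F tests
  # are computed (the benchmark scale concerns variance proportions only)
  fit <- stats::aov(y ~ g)
  sum((stats::fitted(fit) - mean(y))^2) / ss_total
}

#' Interaction eta-squared from a two-way ANOVA
#'
#' Proportion of total variance attributable to the A-by-B interaction:
#' `SS_interaction / SS_total` from the two-way decomposition with both
#' main effects included. The simulation grids produced here are balanced
#' (fully crossed with equal cell counts), where the sequential sums of
#' squares used are orthogonal; unbalanced input triggers a warning.
#'
#' @inheritParams eta_squared_oneway
#' @param factor_a,factor_b names of the two factor columns.
#' @return Eta-squared of the interaction term in \[0, 1\].
#' @export
eta_squared_interaction <- function(grid, factor_a, factor_b,
                                    response = "rate") {
  y <- grid[[response]]
  a <- as.factor(grid[[factor_a]])
  b <- as.factor(grid[[factor_b]])
  cells <- table(a, b)
  if (any(cells == 0L)) {
    miss <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop("no observations for ", factor_a, " = ", levels(a)[miss[1L]],
         ", ", factor_b, " = ", levels(b)[miss[2L]])
  }
  if (length(unique(as.vector(cells))) > 1L)
    warning("design is unbalanced; sequential sums of squares depend on ",
            "factor order")
  ss_total <- sum((y - mean(y))^2)
  if (ss_total == 0) return(0)
  # sequential (type I) interaction SS: RSS drop from adding a:b to the
  # main-effects model
  rss <- function(fit) sum(stats::residuals(fit)^2)
  ss_int <- rss(stats::aov(y ~ a + b)) - rss(stats::aov(y ~ a * b))
  ss_int / ss_total
}

#' Paired-t effect size (Fritz r-squared)
#'
#' Paired-samples t statistic on the differences `x - y` and the variance
#' proportion `r^2 = t^2 / (t^2 + df)` with `df = n - 1`. Used to gauge
#' the effect of a binary design feature (e.g. presence of a
#' mini-reversal) across matched simulation conditions. Degenerate
#' limits: zero-variance differences give `r^2 = 0` when the mean
#' difference is zero and `r^2 = 1` (t infinite) otherwise.
#'
#' @param x,y numeric vectors of equal length `n >= 2`, paired by
#'   condition.
#' @return A list with `t`, `df` and `r2`.
#' @export
#' @examples
#' paired_t_r2(c(2, 3, 4), c(1, 1, 1))  # t = 3.46, r2 = 6/7
paired_t_r2 <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L) stop("at least 2 pairs are required")
  d <- x - y
  df <- n - 1L
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = df, r2 = 0))
    return(list(t = sign(mean(d)) * Inf, df = df, r2 = 1))
  }
  t <- unname(stats::t.test(x, y, paired = TRUE)$statistic)
  list(t = t, df = df, r2 = t^2 / (t^2 + df))
}
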