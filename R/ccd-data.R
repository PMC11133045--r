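#' Construct a changing criterion design series
#'
#' A `ccd_series` holds one observed changing criterion design (CCD) data
#' set: one row per measurement occasion, with the phase the occasion
#' belongs to, the observed score, and the criterion level in force during
#' that phase. The baseline phase, if present, must be the first run of
#' occasions and carries no criterion (all `NA`).
#'
#' @param phase character (or factor) vector of phase identifiers, one per
#'   occasion. Phases must form contiguous runs: once a phase ends it may
#'   not reappear.
#' @param session integer vector of measurement occasions, strictly
#'   increasing. Sessions are carried as metadata; all analysis uses row
#'   order.
#' @param scores numeric vector of observed measurements. Missing scores
#'   are not allowed: neither randomization procedure defines how gaps in
#'   the series are handled.
#' @param criterion numeric vector of criterion levels, constant within
#'   each phase; all `NA` for the baseline phase.
#' @param baseline_label optional phase label to treat as baseline. By
#'   default the baseline is detected as the (first) phase whose criterion
#'   cells are all `NA`.
#'
#' @return An object of class `ccd_series`: a list with elements `phase`,
#'   `session`, `scores`, `criterion`, and `baseline` (the baseline phase
#'   label, or `NA` if the series has no baseline).
#' @seealso [read_ccd()], [strip_baseline()]
#' @export
#' @examples
#' ccd_series(phase = rep(c("A", "B", "C"), each = 3),
#'            session = 1:9,
#'            scores = c(4, 5, 4, 6, 7, 6, 9, 8, 9),
#'            criterion = c(NA, NA, NA, 6, 6, 6, 9, 9, 9))
ccd_series <- function(phase, session, scores, criterion,
                       baseline_label = NULL) {
  phase <- as.character(phase)
  n <- length(phase)
  if (n < 1L)
    stop("a CCD series needs at least one measurement occasion")
  if (length(session) != n || length(scores) != n || length(criterion) != n)
    stop("phase, session, scores and criterion must have equal length")
  if (anyNA(scores) || !is.numeric(scores))
    stop("scores must be numeric with no missing values")
  session <- as.integer(session)
  if (anyNA(session) || any(diff(session) <= 0L))
    stop("sessions must be strictly increasing integers")
  criterion <- as.numeric(criterion)

  runs <- rle(phase)
  if (anyDuplicated(runs$values))
    stop("phases must form contiguous runs; phase '",
         runs$values[anyDuplicated(runs$values)],
         "' appears in more than one run")

  # per-phase criterion must be constant (NA counts as a distinct value)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (i in seq_along(runs$values)) {
    cr <- criterion[starts[i]:ends[i]]
    if (length(unique(cr)) > 1L && !all(is.na(cr)))
      stop("criterion is not constant within phase '", runs$values[i], "'")
  }

  all_na <- vapply(seq_along(runs$values),
                   function(i) all(is.na(criterion[starts[i]:ends[i]])),
                   logical(1))
  if (is.null(baseline_label)) {
    if (sum(all_na) > 1L)
      stop("more than one phase has all-missing criteria; ",
           "use baseline_label to name the baseline")
    baseline <- if (any(all_na)) runs$values[all_na] else NA_character_
  } else {
    baseline <- as.character(baseline_label)
    if (!baseline %in% runs$values)
      stop("baseline_label '", baseline, "' is not a phase in the series")
  }
  if (!is.na(baseline) && baseline != runs$values[1L])
    stop("the baseline phase must be the first run of occasions")

  structure(list(phase = phase, session = session, scores = scores,
                 criterion = criterion, baseline = baseline),
            class = "ccd_series")
}

#' Read a changing criterion series from a delimited text file
#'
#' Reads a table with the four columns `Phase`, `Session`, `Scores` and
#' `Criterion` (case-sensitive, in any column order) and returns a
#' validated [ccd_series()]. The baseline phase is recognised as the first
#' phase whose `Criterion` cells are empty or `NA`, unless
#' `baseline_label` names it explicitly.
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field delimiter; `","` by default, `"\t"` for tab-separated
#'   tables.
#' @inheritParams ccd_series
#' @return A [ccd_series()].
#' @export
read_ccd <- function(path, sep = ",", baseline_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  needed <- c("Phase", "Session", "Scores", "Criterion")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  ccd_series(phase = tab$Phase, session = tab$Session, scores = tab$Scores,
             criterion = tab$Criterion, baseline_label = baseline_label)
}

#' Write a changing criterion series to a delimited text file
#'
#' Writes the `Phase,Session,Scores,Criterion` layout accepted by
#' [read_ccd()]; baseline criteria are written as empty cells.
#'
#' @param series a [ccd_series()].
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_ccd <- function(series, path, sep = ",") {
  stopifnot(inherits(series, "ccd_series"))
  tab <- data.frame(Phase = series$phase, Session = series$session,
                    Scores = series$scores, Criterion = series$criterion)
  utils::write.table(tab, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Construct an intervention-only series
#'
#' The randomization tests operate on the intervention portion of a CCD:
#' the scores after baseline removal, the observed phase lengths, and the
#' criterion level of each intervention phase.
#'
#' @param scores numeric vector of intervention measurements (length `m`).
#' @param phase_lengths positive integers, one per intervention phase,
#'   summing to `m`.
#' @param criterion_levels numeric criterion level per intervention phase,
#'   in temporal order (the assignment actually used in the experiment).
#' @return An object of class `intervention_series`.
#' @seealso [strip_baseline()], [pcm_test()], [bac_test()]
#' @export
intervention_series <- function(scores, phase_lengths, criterion_levels) {
  phase_lengths <- as.integer(phase_lengths)
  if (length(phase_lengths) != length(criterion_levels))
    stop("phase_lengths and criterion_levels must have equal length")
  if (length(phase_lengths) < 2L)
    stop("at least 2 intervention phases are required for a randomization test")
  if (any(phase_lengths < 1L))
    stop("phase lengths must be positive")
  if (sum(phase_lengths) != length(scores))
    stop("phase lengths sum to ", sum(phase_lengths),
         " but there are ", length(scores), " scores")
  if (anyNA(scores) || anyNA(criterion_levels))
    stop("scores and criterion levels must not be missing")
  structure(list(scores = as.numeric(scores),
                 phase_lengths = phase_lengths,
                 criterion_levels = as.numeric(criterion_levels)),
            class = "intervention_series")
}

#' Drop the baseline phase of a CCD series
#'
#' Removes the baseline occasions (which carry no criterion that the
#' scores could be compared to) and extracts the per-phase lengths and
#' criterion levels of the intervention phases in temporal order. If the
#' series has no baseline, all phases are retained.
#'
#' @param series a [ccd_series()].
#' @return An [intervention_series()].
#' @export
strip_baseline <- function(series) {
  stopifnot(inherits(series, "ccd_series"))
  keep <- if (is.na(series$baseline)) rep(TRUE, length(series$phase))
          else series$phase != series$baseline
  if (!any(keep))
    stop("series contains only a baseline phase; nothing to test")
  runs <- rle(series$phase[keep])
  ends <- cumsum(runs$lengths)
  intervention_series(scores = series$scores[keep],
                      phase_lengths = runs$lengths,
                      criterion_levels = series$criterion[keep][ends])
}

#' @export
print.ccd_series <- function(x, ...) {
  runs <- rle(x$phase)
  cat("Changing criterion design series: ", length(x$scores),
      " occasions, ", length(runs$values), " phases", sep = "")
  if (!is.na(x$baseline))
    cat(" (baseline '", x$baseline, "', ",
        runs$lengths[1L], " occasions)", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
print.intervention_series <- function(x, ...) {
  cat("Intervention series: ", length(x$scores), " measurements in ",
      length(x$phase_lengths), " phases\n", sep = "")
  cat("  phase lengths:    ", paste(x$phase_lengths, collapse = ", "), "\n")
  cat("  criterion levels: ", paste(x$criterion_levels, collapse = ", "), "\n")
  invisible(x)
}
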