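#' Flag solution behavior from item-level response times
#'
#' Classifies each person-item response as rapid (`sb = 0`) or effortful
#' (`sb = 1`) by comparing its response time to an item-specific threshold:
#' the empirical percentile (default 10th) of that item's response-time
#' distribution, under the linear-interpolation quantile convention
#' (`stats::quantile` type 7). Responses at or below the threshold are
#' flagged rapid — ties are treated conservatively, as disengagement.
#' Missing response times are presumed effortful (`sb = 1`): absence of
#' timing evidence does not impute disengagement.
#'
#' @param rt Persons x items matrix (or data frame) of response times in
#'   seconds, nonnegative; `NA` cells allowed.
#' @param percentile Percentile defining the per-item rapid threshold, in
#'   \[0, 100\]. Default 10.
#' @return An integer persons x items matrix of solution-behavior flags.
#' @examples
#' rt <- matrix(c(0.5, 2:10), ncol = 1)
#' flag_solution_behavior(rt)  # only the 0.5 s response is rapid
#' @export
flag_solution_behavior <- function(rt, percentile = 10) {
  rt <- as.matrix(rt)
  if (!is.numeric(rt)) stop_invalid("response times must be numeric")
  if (any(rt < 0, na.rm = TRUE)) stop_invalid("response times must be >= 0")
  if (length(percentile) != 1L || !is.finite(percentile) ||
      percentile < 0 || percentile > 100)
    stop_invalid("'percentile' must lie in [0, 100]")
  n_ok <- colSums(!is.na(rt))
  if (any(n_ok < 2L))
    stop_invalid(sprintf("item %d has fewer than 2 non-missing response times",
                         which(n_ok < 2L)[1L]))
  thr <- apply(rt, 2L, stats::quantile, probs = percentile / 100,
               na.rm = TRUE, type = 7, names = FALSE)
  sb <- matrix(1L, nrow(rt), ncol(rt), dimnames = dimnames(rt))
  rapid <- sweep(rt, 2L, thr, `<=`)
  sb[which(rapid)] <- 0L
  sb
}

#' Response-time-effort index
#'
#' Per-person proportion of items answered with solution behavior: the
#' arithmetic mean of the person's solution-behavior flags.
#'
#' @param sb_row Vector of solution-behavior flags in \{0, 1\}, one per item.
#' @return A proportion in \[0, 1\].
#' @examples
#' response_time_effort(c(1, 1, 1, 1, 1, 0, 0))  # 5/7
#' @export
response_time_effort <- function(sb_row) {
  sb_row <- sb_row[!is.na(sb_row)]
  if (length(sb_row) == 0L) stop_invalid("solution-behavior sequence is empty")
  if (!all(sb_row %in% c(0, 1))) stop_invalid("solution-behavior flags must be 0 or 1")
  mean(sb_row)
}

#' Classify persons as rapid or effortful
#'
#' Thresholds the response-time-effort index: persons with `rte >= cutoff`
#' are classified effortful (`rbe = 1`), others rapid (`rbe = 0`). The
#' boundary is inclusive.
#'
#' @param rte Per-person response-time-effort proportions in \[0, 1\].
#' @param cutoff Classification cutoff in \[0, 1\]. Default 0.90.
#' @return Integer vector of rapid/effortful indicators (1 = effortful).
#' @examples
#' classify_persons(c(1, 0.714, 0.9))
#' @export
classify_persons <- function(rte, cutoff = 0.90) {
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff < 0 || cutoff > 1)
    stop_invalid("'cutoff' must lie in [0, 1]")
  if (anyNA(rte) || any(rte < 0 | rte > 1)) stop_invalid("'rte' values must lie in [0, 1]")
  as.integer(rte >= cutoff)
}

#' Effort profile of a sample
#'
#' Derives, from a response-time matrix, the full effort bookkeeping used in
#' effort-moderated scoring: per-cell solution-behavior flags
#' ([flag_solution_behavior()]), the per-person response-time-effort index
#' ([response_time_effort()]), and the per-person rapid/effortful
#' classification ([classify_persons()]).
#'
#' @inheritParams flag_solution_behavior
#' @inheritParams classify_persons
#' @param sb Optional precomputed solution-behavior matrix; when supplied,
#'   `rt` is ignored.
#' @return A list of class `effort_profile` with fields `sb` (persons x
#'   items integer matrix), `rte` (per-person proportion) and `rbe`
#'   (per-person indicator, 1 = effortful).
#' @examples
#' rt <- matrix(rexp(40, 1 / 10), 10, 4)
#' effort_profile(rt)
#' @export
effort_profile <- function(rt = NULL, percentile = 10, cutoff = 0.90, sb = NULL) {
  if (is.null(sb)) {
    if (is.null(rt)) stop_invalid("either 'rt' or 'sb' must be supplied")
    sb <- flag_solution_behavior(rt, percentile = percentile)
  } else {
    sb <- as.matrix(sb)
    if (anyNA(sb) || !all(sb %in% c(0, 1)))
      stop_invalid("solution-behavior flags must be 0 or 1")
    storage.mode(sb) <- "integer"
  }
  rte <- apply(sb, 1L, response_time_effort)
  structure(list(sb = sb, rte = rte, rbe = classify_persons(rte, cutoff)),
            class = "effort_profile")
}

#' @export
print.effort_profile <- function(x, ...) {
  cat(sprintf("Effort profile: %d persons x %d items; %d rapid (rbe = 0), mean RTE %.3f\n",
              nrow(x$sb), ncol(x$sb), sum(x$rbe == 0L), mean(x$rte)))
  invisible(x)
}
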