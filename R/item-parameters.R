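#' Item parameter table
#'
#' Builds the per-item parameter table consumed by every response model:
#' discrimination `a` (slope on the logit scale), difficulty `b` (logits),
#' an ability-guessing slope `k` used by the ability-based guessing models,
#' and an optional lower-asymptote threshold `gamma` on the logit metric.
#' The pseudo-guessing probability `c` is always derived from `gamma` via
#' [gamma_to_c()] and never stored; `gamma = -Inf` is the "no guessing"
#' sentinel under which every 3PL-type model collapses to the 2PL.
#'
#' @param a Numeric vector of discriminations; finite and strictly positive.
#' @param b Numeric vector of difficulties in logits; finite.
#' @param k Ability-guessing slope(s), `>= 0`. Default `0.228`, the value
#'   commonly recommended for four-option multiple choice.
#' @param gamma Lower-asymptote threshold(s) in logits; finite or `-Inf`
#'   (no lower asymptote). Values below `-15` are numerically a zero
#'   asymptote.
#'
#' @return A data frame of class `item_parameters` with columns
#'   `a`, `b`, `k`, `gamma`, one row per item; row order defines the
#'   1-based item index used in all reports.
#'
#' @examples
#' items <- item_parameters(a = 1, b = c(-2, -1, -.5, 0, .5, 1, 2))
#' nrow(items)
#' @export
item_parameters <- function(a, b, k = 0.228, gamma = -Inf) {
  n <- max(length(a), length(b))
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  k <- rep_len(as.numeric(k), n)
  gamma <- rep_len(as.numeric(gamma), n)
  if (n < 1L) stop_invalid("at least one item is required")
  if (anyNA(a) || any(!is.finite(a)) || any(a <= 0))
    stop_invalid("item discrimination 'a' must be finite and > 0")
  if (anyNA(b) || any(!is.finite(b)))
    stop_invalid("item difficulty 'b' must be finite")
  if (anyNA(k) || any(!is.finite(k)) || any(k < 0))
    stop_invalid("ability-guessing slope 'k' must be finite and >= 0")
  if (anyNA(gamma) || any(is.nan(gamma)) || any(gamma == Inf))
    stop_invalid("'gamma' must be finite or -Inf")
  out <- data.frame(a = a, b = b, k = k, gamma = gamma)
  class(out) <- c("item_parameters", "data.frame")
  out
}

#' @export
print.item_parameters <- function(x, ...) {
  cat(sprintf("Item parameters: %d item(s)\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' @keywords internal
as_item_parameters <- function(items) {
  if (inherits(items, "item_parameters")) return(items)
  if (is.data.frame(items) && all(c("a", "b") %in% names(items))) {
    return(item_parameters(
      a = items$a, b = items$b,
      k = if ("k" %in% names(items)) items$k else 0.228,
      gamma = if ("gamma" %in% names(items)) items$gamma else -Inf
    ))
  }
  stop_invalid("'items' must be an item_parameters table (or a data frame with columns a, b)")
}

#' Guessing configuration
#'
#' Fixes the number of response options, the implied random-guessing success
#' rate `g = 1/n_options`, the rapid-responder correction rule, and the slope
#' `k` used by the ability-based rule.
#'
#' @param n_options Integer number of response options, `>= 2`.
#' @param correction One of `"none"`, `"random_guessing"` (rapid responders
#'   are assigned the logit of the random-guessing rate) or
#'   `"ability_based"` (the logit of the guessing rate plus `k` times the
#'   person's effortful-model theta).
#' @param k Slope applied to theta by the ability-based rule and by the
#'   informed-guessing effort-moderated model. Default `0.228`.
#'
#' @return A list of class `guessing_config` with fields `n_options`, `g`,
#'   `correction`, `k`.
#' @examples
#' guessing_config(4, correction = "random_guessing")
#' @export
guessing_config <- function(n_options = 4L,
                            correction = c("none", "random_guessing", "ability_based"),
                            k = 0.228) {
  correction <- match.arg(correction)
  if (length(n_options) != 1L || !is.finite(n_options) ||
      n_options < 2 || n_options != round(n_options))
    stop_invalid("'n_options' must be a single integer >= 2")
  if (length(k) != 1L || !is.finite(k) || k < 0)
    stop_invalid("'k' must be a single finite value >= 0")
  out <- list(n_options = as.integer(n_options), g = 1 / as.integer(n_options),
              correction = correction, k = k)
  class(out) <- "guessing_config"
  out
}

#' @export
print.guessing_config <- function(x, ...) {
  cat(sprintf("Guessing config: %d options (g = %.4f), correction = %s, k = %.3f\n",
              x$n_options, x$g, x$correction, x$k))
  invisible(x)
}

#' Normal prior on theta
#'
#' Prior used by Bayesian modal estimation ([bme_theta()]).
#'
#' @param mean Prior mean in logits. Default 0.
#' @param sd Prior standard deviation in logits, `> 0`. Default 1.
#' @return A list of class `prior_spec`.
#' @examples
#' prior_spec(0, 1)
#' @export
prior_spec <- function(mean = 0, sd = 1) {
  if (length(mean) != 1L || !is.finite(mean)) stop_invalid("prior 'mean' must be finite")
  if (length(sd) != 1L || !is.finite(sd) || sd <= 0) stop_invalid("prior 'sd' must be > 0")
  structure(list(mean = mean, sd = sd), class = "prior_spec")
}
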