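#' @keywords internal
stop_invalid <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("effortirt_invalid_argument", "error", "condition")))
}

#' @keywords internal
stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("effortirt_format_error", "error", "condition")))
}

# probabilities entering a Bernoulli log-likelihood must stay off 0 and 1
PROB_EPS <- 1e-6

#' @keywords internal
clamp_prob <- function(p, eps = PROB_EPS) {
  pmin(pmax(p, eps), 1 - eps)
}
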