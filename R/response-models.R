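#' Two-parameter logistic response probability
#'
#' Probability that a person of ability `theta` answers an item correctly
#' under the 2PL model, `P = exp(a(theta - b)) / (1 + exp(a(theta - b)))`.
#' Evaluated through [stats::plogis()], which is overflow-safe for
#' arbitrarily large `|a(theta - b)|`.
#'
#' @param theta Person ability in logits (scalar or vector conformable with
#'   the item table).
#' @param items An [item_parameters()] table (or a one-row subset).
#' @return Probabilities strictly in (0, 1), one per item (recycled against
#'   `theta` by the usual rules).
#' @examples
#' prob_2pl(0, item_parameters(a = 1, b = 0))       # 0.5
#' prob_2pl(1.2, item_parameters(a = 1, b = -2))    # 0.9608
#' @export
prob_2pl <- function(theta, items) {
  items <- as_item_parameters(items)
  if (anyNA(theta) || any(!is.finite(theta))) stop_invalid("'theta' must be finite")
  stats::plogis(items$a * (theta - items$b))
}

#' Map a logit-metric guessing threshold to a pseudo-guessing probability
#'
#' The lower asymptote `c` of a 3PL item is parameterised on the logit
#' metric as `gamma`, with `c = exp(gamma)/(1 + exp(gamma))`. The sentinel
#' `gamma = -Inf` maps to `c = 0` (no guessing); any `gamma < -15` is a
#' numerically zero asymptote, under which the 3PL reduces to the 2PL.
#'
#' @param gamma Threshold(s) in logits; finite or `-Inf`.
#' @return Probabilities in \[0, 1).
#' @examples
#' gamma_to_c(0)        # 0.5
#' gamma_to_c(-1.0986)  # 0.25
#' @export
gamma_to_c <- function(gamma) {
  if (!is.numeric(gamma) || anyNA(gamma) || any(is.nan(gamma)) || any(gamma == Inf))
    stop_invalid("'gamma' must be numeric, finite or -Inf")
  stats::plogis(gamma)
}

#' Three-parameter logistic response probability
#'
#' `P = c + (1 - c) * prob_2pl(theta, items)`: the 2PL curve lifted by a
#' nonzero lower asymptote `c`, the probability of success for a person of
#' arbitrarily low ability.
#'
#' @inheritParams prob_2pl
#' @param c Pseudo-guessing probability (or vector per item), in \[0, 1).
#' @return Probabilities in (c, 1).
#' @examples
#' prob_3pl(0, item_parameters(a = 1, b = 0), c = 0.25)  # 0.625
#' @export
prob_3pl <- function(theta, items, c) {
  items <- as_item_parameters(items)
  if (!is.numeric(c) || anyNA(c) || any(c < 0) || any(c >= 1))
    stop_invalid("pseudo-guessing 'c' must lie in [0, 1)")
  c + (1 - c) * prob_2pl(theta, items)
}

#' Three-parameter logistic probability on the logit guessing metric
#'
#' The 3PL model written with the item guessing parameter `gamma` on the
#' logit metric; algebraically identical to
#' `prob_3pl(theta, items, gamma_to_c(gamma))`.
#'
#' @inheritParams prob_2pl
#' @return Probabilities in (c, 1) with `c = gamma_to_c(items$gamma)`.
#' @examples
#' prob_3pl_gamma(0, item_parameters(a = 1, b = 0, gamma = 0))  # 0.75
#' @export
prob_3pl_gamma <- function(theta, items) {
  items <- as_item_parameters(items)
  if (anyNA(items$gamma)) stop_invalid("'gamma' must be set for every item")
  prob_3pl(theta, items, gamma_to_c(items$gamma))
}

#' Person-level guessing probability
#'
#' Ability-based guessing rate `c_ij = exp(gamma + k * theta) /
#' (1 + exp(gamma + k * theta))`: the item-level guessing threshold shifted
#' by the person's ability through the slope `k`, so that more able persons
#' guess more successfully. With `k = 0` it collapses to the item-level
#' [gamma_to_c()].
#'
#' @inheritParams prob_2pl
#' @return Guessing probabilities, strictly increasing in `theta` when
#'   `k > 0`.
#' @examples
#' person_guessing(1, item_parameters(a = 1, b = 0, gamma = -1.0986, k = 0.228))
#' @export
person_guessing <- function(theta, items) {
  items <- as_item_parameters(items)
  if (anyNA(theta) || any(!is.finite(theta))) stop_invalid("'theta' must be finite")
  if (anyNA(items$gamma) || anyNA(items$k))
    stop_invalid("'gamma' and 'k' must be set for every item")
  stats::plogis(items$gamma + items$k * theta)
}

#' Ability-based guessing response probability
#'
#' Success probability under the ability-based guessing model:
#' `P = P2 + (1 - P2) * c_ij`, where `P2` is the 2PL probability and `c_ij`
#' the person-level guessing rate of [person_guessing()]. With `k = 0` this
#' is exactly the 3PL model; with `a = 1` it is the fixed-discrimination
#' variant.
#'
#' @inheritParams prob_2pl
#' @return Probabilities in (0, 1).
#' @examples
#' prob_ability_guessing(0, item_parameters(a = 1, b = 0, gamma = -1.0986, k = 0.228))
#' @export
prob_ability_guessing <- function(theta, items) {
  items <- as_item_parameters(items)
  p2 <- prob_2pl(theta, items)
  p2 + (1 - p2) * person_guessing(theta, items)
}

#' Effort-moderated response probability
#'
#' Mixture probability in which effortful responses (`sb = 1`) follow a
#' logistic model and rapid responses (`sb = 0`) follow a guessing rate:
#' \describe{
#'   \item{`em3pl`}{`sb` gates a 3PL curve against the random-guessing rate
#'     `g = 1/n_options`.}
#'   \item{`em2pl`}{`sb` gates a 2PL curve against `g`.}
#'   \item{`em2pl_informed`}{rapid responses earn `k * theta + g` — random
#'     guessing plus an informed-guessing credit proportional to ability.}
#' }
#' The raw informed-guessing term `k * theta + g` is a linear expression
#' that can leave \[0, 1\]; it is clamped to \[1e-6, 1 - 1e-6\] with a
#' warning so that downstream likelihoods stay finite. All returned values
#' are clamped to the same interval.
#'
#' @inheritParams prob_2pl
#' @param sb Solution-behavior flag(s) in \{0, 1\} (1 = effortful), recycled
#'   against items.
#' @param cfg A [guessing_config()]; supplies `g` and (for
#'   `em2pl_informed`) the slope `k`.
#' @param variant One of `"em2pl"`, `"em3pl"`, `"em2pl_informed"`.
#' @return Probabilities in \[1e-6, 1 - 1e-6\].
#' @examples
#' it <- item_parameters(a = 1, b = 0)
#' cfg <- guessing_config(4)
#' prob_effort_moderated(1, it, sb = 0, cfg, "em2pl")           # 0.25
#' prob_effort_moderated(1, it, sb = 0, cfg, "em2pl_informed")  # 0.478
#' @export
prob_effort_moderated <- function(theta, items, sb, cfg,
                                  variant = c("em2pl", "em3pl", "em2pl_informed")) {
  variant <- match.arg(variant)
  items <- as_item_parameters(items)
  if (!inherits(cfg, "guessing_config")) stop_invalid("'cfg' must be a guessing_config")
  sb <- rep_len(as.numeric(sb), nrow(items))
  if (anyNA(sb) || !all(sb %in% c(0, 1)))
    stop_invalid("solution-behavior flags must be 0 or 1")
  solution <- switch(variant,
    em2pl = prob_2pl(theta, items),
    em2pl_informed = prob_2pl(theta, items),
    em3pl = prob_3pl_gamma(theta, items)
  )
  rapid <- switch(variant,
    em2pl = rep_len(cfg$g, nrow(items)),
    em3pl = rep_len(cfg$g, nrow(items)),
    em2pl_informed = {
      raw <- cfg$k * theta + cfg$g
      if (any(sb < 1 & (raw < PROB_EPS | raw > 1 - PROB_EPS)))
        warning("informed-guessing term k*theta + g outside [0, 1]; clamped",
                call. = FALSE)
      raw
    }
  )
  clamp_prob(sb * solution + (1 - sb) * rapid)
}
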