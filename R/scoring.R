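MODEL_VARIANTS <- c("2pl", "3pl", "ability_guessing", "em2pl", "em3pl", "em2pl_informed")

#' @keywords internal
check_model <- function(model) {
  if (length(model) != 1L || !model %in% MODEL_VARIANTS)
    stop_invalid(sprintf("unknown model variant '%s'", paste(model, collapse = ",")))
  model
}

#' @keywords internal
resolve_sb <- function(sb_row, items, model) {
  if (is.null(sb_row)) sb_row <- rep(1, nrow(items))
  sb_row <- rep_len(as.numeric(sb_row), nrow(items))
  if (anyNA(sb_row) || !all(sb_row %in% c(0, 1)))
    stop_invalid("solution-behavior flags must be 0 or 1")
  sb_row
}

#' @keywords internal
need_cfg <- function(cfg, model) {
  if (startsWith(model, "em") && is.null(cfg))
    stop_invalid(sprintf("model '%s' requires a guessing_config", model))
  if (is.null(cfg)) guessing_config(4L) else cfg
}

#' Response probability under a named model variant
#'
#' Dispatches to the response-model functions by name; the common entry
#' point used by the likelihood and the scorer. For effort-moderated
#' variants absent `sb` flags default to all-effortful.
#'
#' @inheritParams prob_2pl
#' @param model One of `"2pl"`, `"3pl"`, `"ability_guessing"`, `"em2pl"`,
#'   `"em3pl"`, `"em2pl_informed"`.
#' @param sb_row Optional solution-behavior flags (1 = effortful).
#' @param cfg A [guessing_config()]; required by effort-moderated variants.
#' @return Per-item probabilities.
#' @export
model_prob <- function(theta, items, model = "2pl", sb_row = NULL, cfg = NULL) {
  check_model(model)
  items <- as_item_parameters(items)
  switch(model,
    "2pl" = prob_2pl(theta, items),
    "3pl" = prob_3pl_gamma(theta, items),
    "ability_guessing" = prob_ability_guessing(theta, items),
    prob_effort_moderated(theta, items, resolve_sb(sb_row, items, model),
                          need_cfg(cfg, model), variant = model)
  )
}

# P and dP/dtheta per item, for the analytic score function. The clamped
# informed-guessing branch has zero derivative where the clamp is active.
#' @keywords internal
prob_and_grad <- function(theta, items, model, sb_row, cfg) {
  a <- items$a
  p2 <- stats::plogis(a * (theta - items$b))
  d2 <- a * p2 * (1 - p2)
  if (model == "2pl") return(list(P = p2, dP = d2))
  if (model == "3pl") {
    cc <- gamma_to_c(items$gamma)
    return(list(P = cc + (1 - cc) * p2, dP = (1 - cc) * d2))
  }
  if (model == "ability_guessing") {
    kk <- items$k
    gg <- stats::plogis(items$gamma + kk * theta)
    return(list(P = p2 + (1 - p2) * gg,
                dP = d2 * (1 - gg) + (1 - p2) * kk * gg * (1 - gg)))
  }
  # effort-moderated variants
  sb <- sb_row
  if (model == "em3pl") {
    cc <- gamma_to_c(items$gamma)
    sol <- cc + (1 - cc) * p2
    dsol <- (1 - cc) * d2
  } else {
    sol <- p2
    dsol <- d2
  }
  if (model == "em2pl_informed") {
    raw <- cfg$k * theta + cfg$g
    rap <- clamp_prob(raw)
    drap <- ifelse(raw > PROB_EPS & raw < 1 - PROB_EPS, cfg$k, 0)
  } else {
    rap <- rep_len(cfg$g, length(sol))
    drap <- rep_len(0, length(sol))
  }
  list(P = sb * sol + (1 - sb) * rap, dP = sb * dsol + (1 - sb) * drap)
}

#' Bernoulli log-likelihood of a response vector
#'
#' Sum over non-missing items of `y log P + (1 - y) log(1 - P)`, with `P`
#' from the selected response model clamped to \[1e-6, 1 - 1e-6\] so the
#' value is always finite. An all-missing vector has log-likelihood 0
#' (empty sum).
#'
#' @inheritParams model_prob
#' @param respv Response vector in \{0, 1, NA\}, one entry per item.
#' @return The log-likelihood value.
#' @examples
#' it <- item_parameters(a = 1, b = 0)
#' log_likelihood(0, 1, it)  # log(0.5)
#' @export
log_likelihood <- function(theta, respv, items, model = "2pl",
                           sb_row = NULL, cfg = NULL) {
  check_model(model)
  items <- as_item_parameters(items)
  respv <- check_respv(respv, items)
  ok <- !is.na(respv)
  if (!any(ok)) return(0)
  p <- clamp_prob(model_prob(theta, items, model, sb_row, cfg))
  sum(respv[ok] * log(p[ok]) + (1 - respv[ok]) * log(1 - p[ok]))
}

#' @keywords internal
check_respv <- function(respv, items) {
  respv <- as.numeric(respv)
  if (length(respv) != nrow(items))
    stop_invalid(sprintf("response vector length %d does not match %d items",
                         length(respv), nrow(items)))
  if (!all(respv %in% c(0, 1) | is.na(respv)))
    stop_invalid("responses must be 0, 1 or missing")
  respv
}

# d/dtheta of the Bernoulli log-likelihood over non-missing items
#' @keywords internal
score_fn <- function(theta, respv, items, model, sb_row, cfg) {
  ok <- !is.na(respv)
  pg <- prob_and_grad(theta, items, model, sb_row, cfg)
  p <- clamp_prob(pg$P)[ok]
  dp <- pg$dP[ok]
  sum((respv[ok] - p) / (p * (1 - p)) * dp)
}

#' Test information at theta
#'
#' Sum of item information values over the non-missing responses. For the
#' 2PL (and the effortful branch of `em2pl`/`em2pl_informed`) the item term
#' is `a^2 P Q`; for 3PL-type models it is the standard expected-information
#' expression `a^2 (Q/P) ((P - c)/(1 - c))^2`, with `c` the item asymptote
#' (3PL variants) or the person-level guessing rate (ability-based model).
#' Rapid cells (`sb = 0`) carry no ability information under `em2pl`/`em3pl`
#' and are excluded; under `em2pl_informed` the rapid branch contributes
#' `k^2 / (P Q)` wherever its linear probability is unclamped.
#'
#' @inheritParams log_likelihood
#' @return The test information value (>= 0).
#' @export
test_information <- function(theta, respv, items, model = "2pl",
                             sb_row = NULL, cfg = NULL) {
  check_model(model)
  items <- as_item_parameters(items)
  respv <- check_respv(respv, items)
  sb <- resolve_sb(sb_row, items, model)
  if (startsWith(model, "em")) cfg <- need_cfg(cfg, model)
  ok <- !is.na(respv)
  a <- items$a
  p2 <- stats::plogis(a * (theta - items$b))
  info <- switch(model,
    "2pl" = a^2 * p2 * (1 - p2),
    "3pl" = ,
    "ability_guessing" = {
      cc <- if (model == "3pl") gamma_to_c(items$gamma) else person_guessing(theta, items)
      p <- cc + (1 - cc) * p2
      a^2 * ((1 - p) / p) * ((p - cc) / (1 - cc))^2
    },
    "em2pl" = sb * a^2 * p2 * (1 - p2),
    "em3pl" = {
      cc <- gamma_to_c(items$gamma)
      p <- cc + (1 - cc) * p2
      sb * a^2 * ((1 - p) / p) * ((p - cc) / (1 - cc))^2
    },
    "em2pl_informed" = {
      raw <- cfg$k * theta + cfg$g
      rap <- clamp_prob(raw)
      unclamped <- raw > PROB_EPS & raw < 1 - PROB_EPS
      sb * a^2 * p2 * (1 - p2) + (1 - sb) * unclamped * cfg$k^2 / (rap * (1 - rap))
    }
  )
  sum(info[ok])
}

# Newton-Raphson maximiser of a log-objective on [lower, upper] with the
# fixed machinery: start 0, step tolerance 1e-6, at most 50 iterations, and
# a bisection fallback on a sign-changing bracket of the score whenever a
# Newton step misbehaves. 3PL-type likelihoods need not be log-concave and
# the informed-guessing mixture has clamp kinks where the score jumps, so
# the routine is safeguarded: candidate optima (Newton from the start,
# Newton or bisection from every sign-changing bracket of the score on a
# coarse grid, and both interval endpoints) are compared on the objective
# and the best is returned.
#' @keywords internal
newton_maximise <- function(score, objective, lower, upper,
                            start = 0, tol = 1e-6, max_iter = 50L) {
  start <- min(max(start, lower), upper)
  n_iter <- 0L
  run_nr <- function(th0) {
    th <- th0
    h <- 1e-5
    for (it in seq_len(max_iter)) {
      s <- score(th)
      hess <- (score(th + h) - score(th - h)) / (2 * h)
      if (!is.finite(s) || !is.finite(hess) || hess >= 0)
        return(list(ok = FALSE, theta = th, n_iter = it))
      step <- -s / hess
      if (!is.finite(step) || abs(step) > (upper - lower))
        return(list(ok = FALSE, theta = th, n_iter = it))
      th_new <- min(max(th + step, lower), upper)
      if (abs(th_new - th) < tol) return(list(ok = TRUE, theta = th_new, n_iter = it))
      th <- th_new
    }
    list(ok = FALSE, theta = th, n_iter = max_iter)
  }
  bisect <- function(lo, hi, slo) {
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      if (sign(score(mid)) == sign(slo)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  candidates <- c(lower, upper)
  res <- run_nr(start)
  n_iter <- n_iter + res$n_iter
  if (res$ok) candidates <- c(candidates, res$theta)
  grid <- seq(lower, upper, length.out = 241L)
  sg <- vapply(grid, score, numeric(1))
  # every downward zero-crossing of the score brackets a local maximum
  # (a kink optimum shows up the same way)
  down <- which(sg[-length(sg)] > 0 & sg[-1] <= 0)
  for (i in down) {
    res_i <- run_nr((grid[i] + grid[i + 1]) / 2)
    n_iter <- n_iter + res_i$n_iter
    cand <- if (res_i$ok && res_i$theta >= grid[i] - 0.1 && res_i$theta <= grid[i + 1] + 0.1)
      res_i$theta
    else
      bisect(grid[i], grid[i + 1], sg[i])
    candidates <- c(candidates, cand)
  }
  ov <- vapply(candidates, objective, numeric(1))
  list(theta = candidates[which.max(ov)], n_iter = max(n_iter, 1L), converged = TRUE)
}

#' @keywords internal
new_theta_estimate <- function(theta, se, method, model, corrected = "none",
                               converged = TRUE, n_iter = 0L, at_boundary = FALSE) {
  structure(list(theta = theta, se = se, method = method, model = model,
                 corrected = corrected, converged = converged,
                 n_iter = as.integer(n_iter), at_boundary = at_boundary),
            class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("theta = %.4f (SE %s), %s/%s%s%s\n",
              x$theta, ifelse(is.na(x$se), "n/a", sprintf("%.4f", x$se)),
              x$method, x$model,
              if (x$corrected != "none") paste0(", corrected: ", x$corrected) else "",
              if (x$at_boundary) ", at boundary" else ""))
  invisible(x)
}

#' Maximum likelihood estimate of theta
#'
#' Newton-Raphson maximisation of the response-vector log-likelihood under
#' the selected model, started at 0 with step tolerance 1e-6, at most 50
#' iterations and a bisection fallback, with the search confined to
#' `+/- log(2 J)` (`J` = item count). Zero-variance vectors cannot be
#' estimated by ML: a vector whose likelihood is still increasing
#' (decreasing) at the upper (lower) bound — in particular all-correct or
#' all-incorrect — is assigned the boundary convention
#' `theta = +log(2 J)` (`-log(2 J)`) with `at_boundary = TRUE`.
#' The standard error is `1 / sqrt(test information)` at the estimate.
#'
#' Under the effort-moderated variants rapid cells contribute a theta-free
#' constant; if no cell carries ability information the likelihood is flat
#' in theta and a non-identifiability error is signalled rather than a
#' spurious estimate.
#'
#' @inheritParams log_likelihood
#' @return A `theta_estimate`: list with `theta`, `se`, `method`, `model`,
#'   `corrected`, `converged`, `n_iter`, `at_boundary`.
#' @examples
#' items <- item_parameters(a = 1, b = c(-2, -1, -.5, 0, .5, 1, 2))
#' mle_theta(c(1, 1, 0, 1, 1, 1, 0), items)
#' @export
mle_theta <- function(respv, items, model = "2pl", sb_row = NULL, cfg = NULL) {
  check_model(model)
  items <- as_item_parameters(items)
  respv <- check_respv(respv, items)
  if (all(is.na(respv))) stop_invalid("no non-missing responses to score")
  sb <- resolve_sb(sb_row, items, model)
  if (startsWith(model, "em")) cfg <- need_cfg(cfg, model)
  bound <- log(2 * nrow(items))
  sc <- function(th) score_fn(th, respv, items, model, sb, cfg)
  ob <- function(th) log_likelihood(th, respv, items, model, sb, cfg)

  ok <- !is.na(respv)
  flat <- model %in% c("em2pl", "em3pl") && all(sb[ok] == 0)
  if (flat)
    stop_invalid("likelihood is flat in theta: every scored response is a rapid cell")

  fit <- newton_maximise(sc, ob, lower = -bound, upper = bound)
  info <- test_information(fit$theta, respv, items, model, sb, cfg)
  at_bound <- abs(abs(fit$theta) - bound) < 1e-8
  theta <- if (at_bound) sign(fit$theta) * bound else fit$theta
  new_theta_estimate(theta, se = if (info > 0) 1 / sqrt(info) else NA_real_,
                     method = "MLE", model = model, converged = fit$converged,
                     n_iter = fit$n_iter, at_boundary = at_bound)
}

#' Bayesian modal estimate of theta
#'
#' Posterior mode of theta under a normal prior: Newton-Raphson
#' maximisation of `log_likelihood + log prior density` with the same
#' machinery as [mle_theta()]. The prior makes every vector estimable — no
#' boundary convention is needed, and an all-missing vector returns the
#' prior mean with the prior sd as its standard error. The standard error
#' is `1 / sqrt(test information + 1/sd^2)` (curvature of the log-posterior
#' under expected information), which is always smaller than the ML
#' standard error on the same data.
#'
#' @inheritParams log_likelihood
#' @param prior A [prior_spec()]; default standard normal.
#' @return A `theta_estimate` with `method = "BME"`.
#' @examples
#' items <- item_parameters(a = 1, b = c(-2, -1, -.5, 0, .5, 1, 2))
#' bme_theta(c(1, 1, 0, 1, 1, 1, 0), items)
#' @export
bme_theta <- function(respv, items, model = "2pl", prior = prior_spec(),
                      sb_row = NULL, cfg = NULL) {
  check_model(model)
  if (!inherits(prior, "prior_spec")) stop_invalid("'prior' must be a prior_spec")
  items <- as_item_parameters(items)
  respv <- check_respv(respv, items)
  sb <- resolve_sb(sb_row, items, model)
  if (startsWith(model, "em")) cfg <- need_cfg(cfg, model)
  if (all(is.na(respv)))
    return(new_theta_estimate(prior$mean, prior$sd, method = "BME", model = model))

  sc <- function(th) score_fn(th, respv, items, model, sb, cfg) - (th - prior$mean) / prior$sd^2
  ob <- function(th) log_likelihood(th, respv, items, model, sb, cfg) +
    stats::dnorm(th, prior$mean, prior$sd, log = TRUE)
  # bracket wide enough that the prior gradient dominates the bounded
  # likelihood score at both ends
  half <- prior$sd^2 * (sum(items$a) + sum(items$k) + 1) + abs(prior$mean) + 1
  fit <- newton_maximise(sc, ob, lower = prior$mean - half, upper = prior$mean + half)
  info <- test_information(fit$theta, respv, items, model, sb, cfg) + 1 / prior$sd^2
  new_theta_estimate(fit$theta, se = 1 / sqrt(info), method = "BME", model = model,
                     converged = fit$converged, n_iter = fit$n_iter)
}

#' Rapid-responder theta correction
#'
#' Replaces the ability estimate of a person classified as rapid
#' (`rbe = 0`) according to the configured correction rule:
#' \describe{
#'   \item{`random_guessing`}{theta becomes the logit of the random-guessing
#'     success rate, `logit(1/n_options)` — identical under MLE and BME and
#'     independent of the response vector.}
#'   \item{`ability_based`}{theta becomes `logit(1/n_options) + k * theta_hat`,
#'     crediting informed guessing proportional to the person's
#'     effortful-model estimate.}
#' }
#' Effortful persons (`rbe = 1`) are returned unchanged. Corrected
#' estimates have no likelihood-based standard error; `se` is `NA`.
#'
#' @param theta_hat A `theta_estimate` from [mle_theta()] or [bme_theta()].
#' @param rbe Person rapid/effortful indicator (1 = effortful, 0 = rapid).
#' @param cfg A [guessing_config()] with `correction != "none"`.
#' @return A `theta_estimate`.
#' @examples
#' it <- item_parameters(a = 1, b = c(-2, -1, -.5, 0, .5, 1, 2))
#' est <- mle_theta(c(1, 1, 0, 1, 1, 1, 0), it)
#' corrected_theta(est, rbe = 0, guessing_config(4, "random_guessing"))
#' @export
corrected_theta <- function(theta_hat, rbe, cfg) {
  if (!inherits(theta_hat, "theta_estimate")) stop_invalid("'theta_hat' must be a theta_estimate")
  if (!inherits(cfg, "guessing_config") || cfg$correction == "none")
    stop_invalid("'cfg' must be a guessing_config with a correction rule selected")
  if (length(rbe) != 1L || is.na(rbe) || !rbe %in% c(0, 1))
    stop_invalid("'rbe' must be 0 or 1")
  if (rbe == 1) return(theta_hat)
  base <- stats::qlogis(cfg$g)
  theta <- switch(cfg$correction,
    random_guessing = base,
    ability_based = base + cfg$k * theta_hat$theta
  )
  new_theta_estimate(theta, se = NA_real_, method = theta_hat$method,
                     model = theta_hat$model, corrected = cfg$correction,
                     converged = TRUE, n_iter = 0L, at_boundary = FALSE)
}

#' Score a sample of response vectors
#'
#' Applies [mle_theta()] or [bme_theta()] to every row of a persons x items
#' response matrix, then [corrected_theta()] wherever the effort profile
#' classifies the person as rapid and a correction rule is configured.
#' Row-level estimation failures are reported per person (NA estimate,
#' `converged = FALSE`) without aborting the batch.
#'
#' @param responses Persons x items matrix (or data frame) of 0/1/NA
#'   responses.
#' @param items An [item_parameters()] table.
#' @param method `"MLE"` or `"BME"`.
#' @param model Response-model variant, see [model_prob()].
#' @param effort Optional [effort_profile()] supplying per-cell `sb` flags
#'   (used by effort-moderated variants) and per-person `rbe`
#'   classifications (used by the correction).
#' @param cfg A [guessing_config()].
#' @param prior A [prior_spec()] (BME only).
#' @param verbose Emit a per-person convergence message.
#' @return A data frame of class `theta_estimates` with columns `person`,
#'   `theta`, `se`, `method`, `model`, `correction`, `converged`, `n_iter`,
#'   `at_boundary`.
#' @examples
#' items <- item_parameters(a = 1, b = c(-1, 0, 1))
#' score_sample(rbind(c(1, 0, 1), c(1, 1, 1)), items)
#' @export
score_sample <- function(responses, items, method = c("MLE", "BME"),
                         model = "2pl", effort = NULL, cfg = NULL,
                         prior = prior_spec(), verbose = FALSE) {
  method <- match.arg(method)
  check_model(model)
  items <- as_item_parameters(items)
  responses <- as.matrix(responses)
  if (ncol(responses) != nrow(items))
    stop_invalid(sprintf("response matrix has %d columns but %d items are defined",
                         ncol(responses), nrow(items)))
  if (!is.null(effort)) {
    if (!inherits(effort, "effort_profile")) stop_invalid("'effort' must be an effort_profile")
    if (nrow(effort$sb) != nrow(responses) || ncol(effort$sb) != ncol(responses))
      stop_invalid("effort profile dimensions do not match the response matrix")
  }
  n <- nrow(responses)
  persons <- if (!is.null(rownames(responses))) rownames(responses) else as.character(seq_len(n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    est <- tryCatch({
      sb_i <- if (!is.null(effort)) effort$sb[i, ] else NULL
      e <- if (method == "MLE") mle_theta(responses[i, ], items, model, sb_i, cfg)
           else bme_theta(responses[i, ], items, model, prior, sb_i, cfg)
      if (!is.null(effort) && !is.null(cfg) && cfg$correction != "none")
        e <- corrected_theta(e, effort$rbe[i], cfg)
      e
    }, error = function(cnd) {
      warning(sprintf("person %s: %s", persons[i], conditionMessage(cnd)), call. = FALSE)
      new_theta_estimate(NA_real_, NA_real_, method, model, converged = FALSE)
    })
    if (verbose)
      message(sprintf("person %s: theta %.4f (%s, %d iterations%s)", persons[i],
                      est$theta, est$method, est$n_iter,
                      if (est$at_boundary) ", boundary" else ""))
    out[[i]] <- data.frame(person = persons[i], theta = est$theta, se = est$se,
                           method = est$method, model = est$model,
                           correction = est$corrected, converged = est$converged,
                           n_iter = est$n_iter, at_boundary = est$at_boundary,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("theta_estimates", "data.frame")
  res
}

#' Total sample log-likelihood at the estimated thetas
#'
#' Sum over persons of the response-vector log-likelihood evaluated at each
#' person's own ML theta estimate — the fit surface on which 2PL and
#' effort-moderated models are compared at fixed item parameters. With all
#' solution-behavior flags equal to 1 the `em2pl` total equals the 2PL
#' total exactly. An empty grid has total 0.
#'
#' @inheritParams score_sample
#' @return The total log-likelihood.
#' @export
sample_log_likelihood <- function(responses, items, model = "2pl",
                                  effort = NULL, cfg = NULL) {
  check_model(model)
  items <- as_item_parameters(items)
  responses <- as.matrix(responses)
  if (nrow(responses) == 0L) return(0)
  if (ncol(responses) != nrow(items))
    stop_invalid(sprintf("response matrix has %d columns but %d items are defined",
                         ncol(responses), nrow(items)))
  total <- 0
  for (i in seq_len(nrow(responses))) {
    sb_i <- if (!is.null(effort)) effort$sb[i, ] else NULL
    # a fully-rapid row has a theta-free em likelihood; any theta evaluates it
    th_i <- tryCatch(mle_theta(responses[i, ], items, model, sb_i, cfg)$theta,
                     error = function(cnd) 0)
    total <- total + log_likelihood(th_i, responses[i, ], items, model, sb_i, cfg)
  }
  total
}
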