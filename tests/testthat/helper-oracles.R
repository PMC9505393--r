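# Independent oracles: direct textbook formulas and brute-force search,
# written without reference to the package's own evaluation path.

oracle_logistic <- function(x) exp(x) / (1 + exp(x))

oracle_p2 <- function(theta, a, b) oracle_logistic(a * (theta - b))

oracle_p3 <- function(theta, a, b, cc) cc + (1 - cc) * oracle_p2(theta, a, b)

oracle_ability_guess <- function(theta, a, b, gamma, k) {
  p2 <- oracle_p2(theta, a, b)
  p2 + (1 - p2) * oracle_logistic(gamma + k * theta)
}

# per-item probability under any variant, brute force
oracle_model_p <- function(theta, a, b, gamma, k, sb, g, model) {
  eps <- 1e-6
  p <- switch(model,
    "2pl" = oracle_p2(theta, a, b),
    "3pl" = oracle_p3(theta, a, b, oracle_logistic(gamma)),
    "ability_guessing" = oracle_ability_guess(theta, a, b, gamma, k),
    "em2pl" = sb * oracle_p2(theta, a, b) + (1 - sb) * g,
    "em3pl" = sb * oracle_p3(theta, a, b, oracle_logistic(gamma)) + (1 - sb) * g,
    "em2pl_informed" = sb * oracle_p2(theta, a, b) +
      (1 - sb) * pmin(pmax(k * theta + g, eps), 1 - eps)
  )
  pmin(pmax(p, eps), 1 - eps)
}

# brute-force double-loop Bernoulli log-likelihood
oracle_loglik <- function(theta, y, a, b, gamma = -Inf, k = 0.228,
                          sb = rep(1, length(y)), g = 0.25, model = "2pl") {
  total <- 0
  for (i in seq_along(y)) {
    if (is.na(y[i])) next
    p <- oracle_model_p(theta, a[i], b[i], gamma[min(i, length(gamma))],
                        k, sb[i], g, model)
    total <- total + y[i] * log(p) + (1 - y[i]) * log(1 - p)
  }
  total
}

# grid-search argmax of an objective, step 1e-4 unless stated otherwise
oracle_grid_argmax <- function(objective, lower, upper, step = 1e-4) {
  grid <- seq(lower, upper, by = step)
  vals <- vapply(grid, objective, numeric(1))
  grid[which.max(vals)]
}

# vectorised grid-search argmax of a response-vector log-likelihood
# (loops items, vectorised over the theta grid; independent of the scorer)
oracle_grid_mle <- function(y, a, b, gamma = -Inf, k = 0.228,
                            sb = rep(1, length(y)), g = 0.25, model = "2pl",
                            lower, upper, step = 1e-4,
                            log_prior = function(th) 0) {
  grid <- seq(lower, upper, by = step)
  total <- log_prior(grid)
  if (length(total) == 1L) total <- rep(total, length(grid))
  for (i in seq_along(y)) {
    if (is.na(y[i])) next
    p <- oracle_model_p(grid, a[i], b[i], gamma[min(i, length(gamma))],
                        k, sb[i], g, model)
    total <- total + y[i] * log(p) + (1 - y[i]) * log(1 - p)
  }
  grid[which.max(total)]
}

# sort-and-count quantile-rule oracle: the flags a threshold rule should give
oracle_flag_rapid <- function(times, prob) {
  thr <- stats::quantile(times, probs = prob, na.rm = TRUE, type = 7, names = FALSE)
  ifelse(is.na(times), 1L, as.integer(times > thr))
}
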