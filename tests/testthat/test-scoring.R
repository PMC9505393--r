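test_that("log-likelihood matches a brute-force summation oracle", {
  it <- items7()
  y <- respv9()
  expect_equal(log_likelihood(0, rep(NA, 7), it), 0)
  expect_equal(log_likelihood(0, 1, item_parameters(1, 0)), log(0.5))
  for (t in c(-2, 0, 0.7, 3))
    expect_equal(log_likelihood(t, y, it),
                 oracle_loglik(t, y, it$a, it$b), tolerance = 1e-12)
  # missing responses drop out of the sum
  y_na <- y; y_na[c(2, 5)] <- NA
  expect_equal(log_likelihood(1, y_na, it), oracle_loglik(1, y_na, it$a, it$b),
               tolerance = 1e-12)
  expect_error(log_likelihood(0, c(1, 0), it), class = "effortirt_invalid_argument")
  expect_error(log_likelihood(0, c(1, 2, 0, 1, 1, 1, 0), it),
               class = "effortirt_invalid_argument")
})

test_that("worked seven-item vector reproduces the grid-search oracle values", {
  it <- items7()
  y <- respv9()
  L <- log(14)
  th_star <- oracle_grid_mle(y, it$a, it$b, model = "2pl", lower = -L, upper = L)
  est <- mle_theta(y, it)
  expect_lt(abs(est$theta - th_star), 1e-3)
  # frozen pre-build oracle values
  expect_equal(est$theta, 1.1972, tolerance = 1e-3)
  expect_equal(est$se, 0.9449, tolerance = 1e-3)
  expect_equal(est$se, 1 / sqrt(sum(it$a^2 * oracle_p2(est$theta, it$a, it$b) *
                                      (1 - oracle_p2(est$theta, it$a, it$b)))),
               tolerance = 1e-6)

  th_bstar <- oracle_grid_mle(y, it$a, it$b, model = "2pl", lower = -6, upper = 6,
                              log_prior = function(th) dnorm(th, 0, 1, log = TRUE))
  best <- bme_theta(y, it)
  expect_lt(abs(best$theta - th_bstar), 1e-3)
  expect_equal(best$theta, 0.6517, tolerance = 1e-3)
  expect_equal(best$se, 0.6653, tolerance = 1e-3)
})

test_that("zero-variance vectors take the boundary convention theta = +/- log(2J)", {
  it <- items7()
  up <- mle_theta(rep(1, 7), it)
  expect_identical(up$theta, log(14))
  expect_true(up$at_boundary)
  expect_equal(up$theta, 2.639, tolerance = 1e-3)
  dn <- mle_theta(rep(0, 7), it)
  expect_identical(dn$theta, -log(14))
  expect_true(dn$at_boundary)
  # BME needs no boundary: the prior keeps the mode interior
  bup <- bme_theta(rep(1, 7), it)
  expect_false(bup$at_boundary)
  expect_lt(bup$theta, log(14))
  expect_error(mle_theta(rep(NA, 7), it), class = "effortirt_invalid_argument")
  # all-missing BME returns the prior
  bm <- bme_theta(rep(NA, 7), it, prior = prior_spec(0.3, 1.4))
  expect_equal(bm$theta, 0.3)
  expect_equal(bm$se, 1.4)
})

test_that("Rasch scoring is a strictly increasing function of the raw score", {
  it <- items7()
  vecs <- all_vectors(7)
  raw <- rowSums(vecs)
  interior <- raw > 0 & raw < 7
  mle <- apply(vecs[interior, ], 1, function(y) mle_theta(y, it)$theta)
  bme_th <- apply(vecs[interior, ], 1, function(y) bme_theta(y, it)$theta)
  mle_se <- apply(vecs[interior, ], 1, function(y) mle_theta(y, it)$se)
  bme_se <- apply(vecs[interior, ], 1, function(y) bme_theta(y, it)$se)
  score <- raw[interior]
  # raw score is sufficient: same score, same theta
  for (s in 1:6)
    expect_lt(diff(range(mle[score == s])), 1e-5)
  # strictly increasing across scores
  for (s in 1:5)
    expect_lt(max(mle[score == s]), min(mle[score == s + 1]))
  # shrinkage: BME closer to the prior mean, BME SE below MLE SE
  expect_true(all(bme_se < mle_se))
  expect_true(all(abs(bme_th) <= abs(mle) + 1e-8))
})

test_that("score equation is satisfied at every interior optimum", {
  it <- items7()
  vecs <- all_vectors(7)
  raw <- rowSums(vecs)
  interior <- which(raw > 0 & raw < 7)
  h <- 1e-6
  for (i in interior[seq(1, length(interior), by = 7)]) {
    y <- vecs[i, ]
    th <- mle_theta(y, it)$theta
    if (abs(th) < log(14) - 1e-6) {
      num_score <- (log_likelihood(th + h, y, it) - log_likelihood(th - h, y, it)) / (2 * h)
      expect_lt(abs(num_score), 1e-5)
    }
    thb <- bme_theta(y, it)$theta
    num_score_b <- (log_likelihood(thb + h, y, it) + dnorm(thb + h, log = TRUE) -
                      log_likelihood(thb - h, y, it) - dnorm(thb - h, log = TRUE)) / (2 * h)
    expect_lt(abs(num_score_b), 1e-5)
  }
})

test_that("Newton-Raphson matches the grid-search oracle on random instances", {
  set.seed(909)
  models <- c("2pl", "3pl", "ability_guessing", "em2pl", "em3pl", "em2pl_informed")
  n_bad <- 0
  for (trial in 1:200) {
    J <- sample(4:10, 1)
    it <- item_parameters(a = runif(J, 0.5, 2.5), b = runif(J, -3, 3),
                          gamma = runif(1, -3, -0.5), k = 0.228)
    model <- models[(trial %% length(models)) + 1]
    cfg <- guessing_config(4)
    sb <- rep(1, J)
    if (startsWith(model, "em")) {
      sb <- rbinom(J, 1, 0.8)
      if (sum(sb) < 2) sb[sample(J, 2)] <- 1
    }
    th_true <- rnorm(1)
    p <- vapply(seq_len(J), function(i)
      suppressWarnings(model_prob(th_true, it[i, ], model, sb[i], cfg)), numeric(1))
    y <- as.integer(runif(J) < p)
    L <- log(2 * J)
    est <- suppressWarnings(mle_theta(y, it, model, sb, cfg))
    oracle <- oracle_grid_mle(y, it$a, it$b, gamma = it$gamma, k = 0.228,
                              sb = sb, g = 0.25, model = model,
                              lower = -L, upper = L)
    # the informed-guessing mixture has clamp kinks where the score jumps;
    # the score-equation check only applies at smooth interior optima
    kinks <- c((1e-6 - cfg$g) / cfg$k, (1 - 1e-6 - cfg$g) / cfg$k)
    at_kink <- function(th) model == "em2pl_informed" && any(sb == 0) &&
      min(abs(th - kinks)) < 2e-3
    if (est$at_boundary) {
      expect_lt(abs(abs(oracle) - L), 2e-4)
    } else {
      expect_lt(abs(est$theta - oracle), 1e-3)
      if (!at_kink(est$theta)) {
        h <- 1e-6
        num_score <- (suppressWarnings(log_likelihood(est$theta + h, y, it, model, sb, cfg)) -
                      suppressWarnings(log_likelihood(est$theta - h, y, it, model, sb, cfg))) / (2 * h)
        expect_lt(abs(num_score), 1e-5)
      }
    }
    best <- suppressWarnings(bme_theta(y, it, model, prior_spec(), sb, cfg))
    boracle <- oracle_grid_mle(y, it$a, it$b, gamma = it$gamma, k = 0.228,
                               sb = sb, g = 0.25, model = model,
                               lower = -8, upper = 8,
                               log_prior = function(th) dnorm(th, log = TRUE))
    expect_lt(abs(best$theta - boracle), 1e-3)
  }
})

test_that("a fully rapid row under em2pl is reported as non-identifiable", {
  it <- items7()
  expect_error(mle_theta(respv9(), it, "em2pl", sb_row = rep(0, 7),
                         cfg = guessing_config(4)),
               "flat", class = "effortirt_invalid_argument")
  # em likelihood with all flags effortful equals the plain model
  y <- respv9()
  for (t in c(-1, 0.4, 2))
    expect_equal(log_likelihood(t, y, it, "em2pl", rep(1, 7), guessing_config(4)),
                 log_likelihood(t, y, it, "2pl"), tolerance = 1e-12)
})

test_that("rapid-responder corrections follow the configured rule", {
  it <- items7()
  est <- mle_theta(respv9(), it)
  cfg4 <- guessing_config(4, "random_guessing")
  cor4 <- corrected_theta(est, rbe = 0, cfg4)
  expect_equal(cor4$theta, qlogis(0.25))
  expect_equal(round(cor4$theta, 3), -1.099)
  expect_true(is.na(cor4$se))
  expect_equal(cor4$corrected, "random_guessing")
  expect_false(cor4$at_boundary)
  # identical under BME
  expect_equal(corrected_theta(bme_theta(respv9(), it), 0, cfg4)$theta, qlogis(0.25))
  # two options: logit(0.5) = 0
  expect_equal(corrected_theta(est, 0, guessing_config(2, "random_guessing"))$theta, 0)
  # ability-based: logit(g) + k * theta_hat
  cfg_ab <- guessing_config(4, "ability_based", k = 0.228)
  fake <- effortirt:::new_theta_estimate(1.015, 0.927, "MLE", "2pl")
  expect_equal(corrected_theta(fake, 0, cfg_ab)$theta, qlogis(0.25) + 0.228 * 1.015)
  expect_equal(round(corrected_theta(fake, 0, cfg_ab)$theta, 3), -0.867)
  # effortful person is untouched
  expect_identical(corrected_theta(est, 1, cfg4), est)
  expect_error(corrected_theta(est, 0, guessing_config(4, "none")),
               class = "effortirt_invalid_argument")
  expect_error(corrected_theta(est, 2, cfg4), class = "effortirt_invalid_argument")
})

test_that("batch scoring is a map over persons with per-row error reporting", {
  it <- items7()
  y <- respv9()
  grid1 <- matrix(y, nrow = 1)
  single <- score_sample(grid1, it)
  expect_equal(single$theta, mle_theta(y, it)$theta)
  expect_equal(single$se, mle_theta(y, it)$se)

  # all-effortful effort profile is a no-op relative to effort = none
  resp <- rbind(y, c(0, 1, 1, 0, 1, 0, 1), rep(1, 7))
  prof <- effort_profile(sb = matrix(1L, 3, 7))
  cfg <- guessing_config(4, "random_guessing")
  with_eff <- score_sample(resp, it, effort = prof, cfg = cfg)
  without <- score_sample(resp, it)
  expect_equal(with_eff$theta, without$theta)
  expect_equal(with_eff$se, without$se)

  # a rapid person is corrected, others untouched
  prof2 <- effort_profile(sb = matrix(1L, 3, 7))
  prof2$rbe <- c(1L, 0L, 1L)
  mixed <- score_sample(resp, it, effort = prof2, cfg = cfg)
  expect_equal(mixed$theta[2], qlogis(0.25))
  expect_equal(mixed$correction, c("none", "random_guessing", "none"))
  expect_equal(mixed$theta[c(1, 3)], without$theta[c(1, 3)])

  # a row with no scoreable responses fails alone, the batch continues
  resp_bad <- matrix(c(y, rep(NA, 7)), nrow = 2, byrow = TRUE)
  expect_warning(batch <- score_sample(resp_bad, it), "person 2")
  expect_true(is.na(batch$theta[2]))
  expect_false(batch$converged[2])
  expect_equal(batch$theta[1], mle_theta(y, it)$theta)
})

test_that("sample log-likelihood reduces to the plain model when effort is uniform", {
  it <- items7()
  set.seed(31)
  resp <- matrix(rbinom(5 * 7, 1, 0.5), 5, 7)
  # keep rows interior so the totals are comparable at the same optimum
  resp[, 1] <- 1
  resp[, 7] <- 0
  prof <- effort_profile(sb = matrix(1L, 5, 7))
  cfg <- guessing_config(4)
  expect_equal(sample_log_likelihood(resp, it, "em2pl", prof, cfg),
               sample_log_likelihood(resp, it, "2pl"), tolerance = 1e-9)
  expect_equal(sample_log_likelihood(matrix(numeric(0), 0, 7), it), 0)
  # brute-force double-loop oracle on a small random grid
  it3 <- item_parameters(a = c(0.8, 1.2, 1.6), b = c(-1, 0, 1))
  resp3 <- matrix(rbinom(15, 1, 0.5), 5, 3)
  total <- 0
  for (i in 1:5) {
    th_i <- mle_theta(resp3[i, ], it3)$theta
    total <- total + oracle_loglik(th_i, resp3[i, ], it3$a, it3$b)
  }
  expect_equal(sample_log_likelihood(resp3, it3), total, tolerance = 1e-9)
})
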