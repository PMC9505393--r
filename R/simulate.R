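#' Simulation design
#'
#' Describes a synthetic dataset: engaged persons respond under a 2PL model
#' at abilities drawn from `N(theta_mean, theta_sd^2)`, a fraction of
#' persons are rapid responders whose rapid cells are Bernoulli draws at
#' the random-guessing rate `1/n_options`, and every cell gets a response
#' time from a lognormal whose parameters depend on whether the cell is
#' rapid or engaged. The rapid time component must be stochastically
#' smaller than the engaged one (`mu_rapid < mu_engaged`).
#'
#' @param n_persons Number of persons.
#' @param items An [item_parameters()] table.
#' @param theta_mean,theta_sd Generating ability distribution (logits);
#'   `theta_sd > 0`.
#' @param rapid_person_rate Proportion of persons who are rapid responders,
#'   in \[0, 1\]. Default 0.2.
#' @param rapid_item_rate_given_rapid Proportion of a rapid person's items
#'   answered rapidly, in \[0, 1\]. Default 1 (fully rapid rows).
#' @param n_options Response options; sets the guessing rate of rapid cells.
#' @param rt_lognormal_mu_engaged,rt_lognormal_sigma_engaged Lognormal
#'   response-time parameters (log-seconds) for engaged cells; defaults
#'   `log(20)` and 0.5.
#' @param rt_lognormal_mu_rapid,rt_lognormal_sigma_rapid Same for rapid
#'   cells; defaults `log(2)` and 0.4.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A list of class `simulation_design`.
#' @examples
#' simulation_design(200, item_parameters(a = 1, b = c(-2, -1, -.5, 0, .5, 1, 2)))
#' @export
simulation_design <- function(n_persons, items, theta_mean = 0, theta_sd = 1,
                              rapid_person_rate = 0.2,
                              rapid_item_rate_given_rapid = 1,
                              n_options = 4L,
                              rt_lognormal_mu_engaged = log(20),
                              rt_lognormal_sigma_engaged = 0.5,
                              rt_lognormal_mu_rapid = log(2),
                              rt_lognormal_sigma_rapid = 0.4,
                              seed = 1L) {
  items <- as_item_parameters(items)
  if (length(n_persons) != 1L || !is.finite(n_persons) || n_persons < 1)
    stop_invalid("'n_persons' must be a positive integer")
  if (!is.finite(theta_mean) || !is.finite(theta_sd) || theta_sd <= 0)
    stop_invalid("theta distribution parameters must be finite with sd > 0")
  for (r in c(rapid_person_rate, rapid_item_rate_given_rapid))
    if (!is.finite(r) || r < 0 || r > 1) stop_invalid("rates must lie in [0, 1]")
  if (rt_lognormal_sigma_engaged <= 0 || rt_lognormal_sigma_rapid <= 0)
    stop_invalid("lognormal sigma parameters must be > 0")
  if (rt_lognormal_mu_rapid >= rt_lognormal_mu_engaged)
    stop_invalid("rapid response times must be stochastically smaller (mu_rapid < mu_engaged)")
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop_invalid("'seed' must be a single integer")
  structure(list(
    n_persons = as.integer(n_persons), items = items,
    theta_mean = theta_mean, theta_sd = theta_sd,
    rapid_person_rate = rapid_person_rate,
    rapid_item_rate_given_rapid = rapid_item_rate_given_rapid,
    n_options = as.integer(n_options),
    rt_lognormal_mu_engaged = rt_lognormal_mu_engaged,
    rt_lognormal_sigma_engaged = rt_lognormal_sigma_engaged,
    rt_lognormal_mu_rapid = rt_lognormal_mu_rapid,
    rt_lognormal_sigma_rapid = rt_lognormal_sigma_rapid,
    seed = as.integer(seed)
  ), class = "simulation_design")
}

#' Simulate a dataset with a rapid-guessing mixture
#'
#' Draws, in a fixed documented order from one seeded generator — person
#' thetas, rapid-person indicators, rapid-cell indicators, response
#' uniforms, response-time normals — so that the same design yields a
#' bit-identical dataset. Engaged cells (`true_sb = 1`) are Bernoulli draws
#' at the 2PL probability of the person's true theta; rapid cells are
#' Bernoulli draws at the random-guessing rate `1/n_options`. Response
#' times come from the engaged or rapid lognormal component per cell.
#'
#' @param design A [simulation_design()].
#' @return A list of class `simulated_dataset` with fields `responses`
#'   (persons x items 0/1 matrix), `times` (persons x items seconds),
#'   `true_theta`, `true_sb` (persons x items flags), `true_rbe`
#'   (per-person indicator, 1 = effortful) and `design`.
#' @examples
#' d <- simulation_design(20, item_parameters(a = 1, b = 0:2), seed = 7)
#' sim <- simulate_dataset(d)
#' dim(sim$responses)
#' @export
simulate_dataset <- function(design) {
  if (!inherits(design, "simulation_design")) stop_invalid("'design' must be a simulation_design")
  n <- design$n_persons
  J <- nrow(design$items)
  g <- 1 / design$n_options
  set.seed(design$seed)
  theta <- stats::rnorm(n, design$theta_mean, design$theta_sd)
  is_rapid_person <- stats::rbinom(n, 1L, design$rapid_person_rate)
  rapid_cell <- matrix(stats::rbinom(n * J, 1L, design$rapid_item_rate_given_rapid), n, J)
  sb <- 1L - is_rapid_person * rapid_cell
  p_engaged <- t(vapply(theta, function(th) prob_2pl(th, design$items), numeric(J)))
  p <- sb * p_engaged + (1 - sb) * g
  responses <- matrix(as.integer(stats::runif(n * J) < p), n, J)
  z <- matrix(stats::rnorm(n * J), n, J)
  mu <- ifelse(sb == 1L, design$rt_lognormal_mu_engaged, design$rt_lognormal_mu_rapid)
  sig <- ifelse(sb == 1L, design$rt_lognormal_sigma_engaged, design$rt_lognormal_sigma_rapid)
  times <- exp(mu + sig * z)
  dimnames(responses) <- dimnames(times) <- dimnames(sb) <-
    list(as.character(seq_len(n)), paste0("I", seq_len(J)))
  structure(list(responses = responses, times = times, true_theta = theta,
                 true_sb = sb, true_rbe = 1L - is_rapid_person, design = design),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d persons x %d items, %d rapid person(s), seed %d\n",
              nrow(x$responses), ncol(x$responses), sum(x$true_rbe == 0L),
              x$design$seed))
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' For each replication: simulate a dataset from the design, derive an
#' effort profile from the simulated response times (item-level percentile
#' flagging plus the RTE cutoff), score the sample under the requested
#' method/model/correction, and summarise estimation error against the
#' generating thetas. Summaries (mean signed bias and RMSE of estimated vs.
#' true theta) are reported overall and split by true rapid status.
#' Replication `r` uses seed `design$seed + r - 1`; results are
#' deterministic given the design.
#'
#' Persons whose theta could not be estimated (non-converged rows) are
#' excluded from the summaries, with their count reported.
#'
#' @param design A [simulation_design()].
#' @param method `"MLE"` or `"BME"`.
#' @param model Response-model variant used for scoring.
#' @param correction Correction rule, as in [guessing_config()].
#' @param n_replications Number of replications, `>= 1`.
#' @param percentile,rte_cutoff Effort-flagging parameters, see
#'   [effort_profile()].
#' @param prior Prior for BME scoring.
#' @param use_effort Use the response-time effort profile during scoring;
#'   set `FALSE` for naive scoring that ignores response times.
#' @return A data frame of class `recovery_report`: one row per replication
#'   x group (`all`, `effortful`, `rapid`) with columns `n`, `n_failed`,
#'   `bias`, `rmse`.
#' @examples
#' d <- simulation_design(50, item_parameters(a = 1, b = seq(-2, 2, length.out = 10)),
#'                        rapid_person_rate = 0, seed = 3)
#' recovery_experiment(d)
#' @export
recovery_experiment <- function(design, method = c("MLE", "BME"), model = "2pl",
                                correction = c("none", "random_guessing", "ability_based"),
                                n_replications = 1L, percentile = 10,
                                rte_cutoff = 0.90, prior = prior_spec(),
                                use_effort = TRUE) {
  if (!inherits(design, "simulation_design")) stop_invalid("'design' must be a simulation_design")
  method <- match.arg(method)
  correction <- match.arg(correction)
  check_model(model)
  if (n_replications < 1) stop_invalid("'n_replications' must be >= 1")
  cfg <- guessing_config(design$n_options, correction)
  rows <- list()
  for (r in seq_len(n_replications)) {
    d_r <- design
    d_r$seed <- design$seed + r - 1L
    sim <- simulate_dataset(d_r)
    eff <- if (use_effort)
      effort_profile(sim$times, percentile = percentile, cutoff = rte_cutoff)
    else NULL
    est <- suppressWarnings(
      score_sample(sim$responses, design$items, method = method, model = model,
                   effort = eff, cfg = cfg, prior = prior))
    summarise <- function(idx, group) {
      ok <- idx & est$converged & !is.na(est$theta)
      err <- est$theta[ok] - sim$true_theta[ok]
      data.frame(replication = r, group = group, n = sum(idx),
                 n_failed = sum(idx & !ok),
                 bias = if (any(ok)) mean(err) else NA_real_,
                 rmse = if (any(ok)) sqrt(mean(err^2)) else NA_real_,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- summarise(rep(TRUE, nrow(est)), "all")
    rows[[length(rows) + 1L]] <- summarise(sim$true_rbe == 1L, "effortful")
    rows[[length(rows) + 1L]] <- summarise(sim$true_rbe == 0L, "rapid")
  }
  out <- do.call(rbind, rows)
  class(out) <- c("recovery_report", "data.frame")
  out
}
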