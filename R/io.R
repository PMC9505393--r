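#' Read an item parameter file
#'
#' Headered CSV with required columns `a`, `b`, `k` (discrimination,
#' difficulty, ability-guessing slope) and an optional `gamma` column
#' (logit-metric lower-asymptote threshold). A missing `gamma` column means
#' no lower asymptote (`gamma = -Inf`). Row order defines the 1-based item
#' index.
#'
#' @param path Path to the CSV file.
#' @return An [item_parameters()] table.
#' @export
read_item_parameters <- function(path) {
  df <- read_checked_csv(path)
  missing_cols <- setdiff(c("a", "b", "k"), names(df))
  if (length(missing_cols) > 0L)
    stop_format(sprintf("%s: missing required column(s): %s", path,
                        paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0L) stop_format(sprintf("%s: no item rows (header only)", path))
  for (col in intersect(c("a", "b", "k", "gamma"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad) > 0L)
      stop_format(sprintf("%s: non-numeric value in column '%s', row %d",
                          path, col, bad[1L]))
    if (anyNA(v))
      stop_format(sprintf("%s: empty cell in column '%s', row %d",
                          path, col, which(is.na(v))[1L]))
    df[[col]] <- v
  }
  item_parameters(a = df$a, b = df$b, k = df$k,
                  gamma = if ("gamma" %in% names(df)) df$gamma else -Inf)
}

#' @keywords internal
read_checked_csv <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 colClasses = "character", check.names = FALSE),
                 error = function(cnd) stop_format(sprintf("%s: %s", path,
                                                           conditionMessage(cnd))))
  names(df) <- trimws(names(df))
  df
}

# split an optional person-identifier column from a person x item table
#' @keywords internal
split_person_column <- function(df) {
  has_id <- length(df) > 0L && tolower(names(df)[1L]) %in% c("person", "id")
  ids <- if (has_id) as.character(df[[1L]]) else as.character(seq_len(nrow(df)))
  list(ids = ids, data = if (has_id) df[-1L] else df)
}

#' Read a response matrix
#'
#' Headered CSV with persons as rows and items as columns; cells must be
#' `0`, `1` or empty (missing). An optional leading `person` (or `id`)
#' column supplies person identifiers; otherwise persons are numbered 1..n.
#'
#' @param path Path to the CSV file.
#' @return A persons x items matrix of 0/1/NA with person identifiers as
#'   row names.
#' @export
read_responses <- function(path) {
  parts <- split_person_column(read_checked_csv(path))
  df <- parts$data
  if (length(df) == 0L) stop_format(sprintf("%s: no item columns", path))
  m <- matrix(NA_real_, nrow(df), length(df),
              dimnames = list(parts$ids, names(df)))
  for (j in seq_along(df)) {
    raw <- trimws(df[[j]])
    empty <- is.na(raw) | raw == ""
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!empty & (is.na(v) | !(v %in% c(0, 1))))
    if (length(bad) > 0L)
      stop_format(sprintf("%s: non-binary response in column '%s', row %d",
                          path, names(df)[j], bad[1L]))
    m[, j] <- ifelse(empty, NA_real_, v)
  }
  m
}

#' Read a response-time matrix
#'
#' Headered CSV, persons as rows and items as columns, values in seconds
#' (nonnegative decimals); empty cells are missing. An optional leading
#' `person`/`id` column is handled as in [read_responses()].
#'
#' @param path Path to the CSV file.
#' @return A persons x items numeric matrix with NA for missing cells.
#' @export
read_response_times <- function(path) {
  parts <- split_person_column(read_checked_csv(path))
  df <- parts$data
  if (length(df) == 0L) stop_format(sprintf("%s: no item columns", path))
  m <- matrix(NA_real_, nrow(df), length(df),
              dimnames = list(parts$ids, names(df)))
  for (j in seq_along(df)) {
    raw <- trimws(df[[j]])
    empty <- is.na(raw) | raw == ""
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!empty & (is.na(v) | v < 0))
    if (length(bad) > 0L)
      stop_format(sprintf("%s: invalid response time in column '%s', row %d",
                          path, names(df)[j], bad[1L]))
    m[, j] <- ifelse(empty, NA_real_, v)
  }
  m
}

#' Read a per-person rapid/effortful vector
#'
#' CSV with a `rbe` column (1 = effortful, 0 = rapid) and an optional
#' `person`/`id` column.
#'
#' @param path Path to the CSV file.
#' @return An integer vector of indicators, named by person identifier.
#' @export
read_rbe <- function(path) {
  df <- read_checked_csv(path)
  if (!"rbe" %in% names(df)) stop_format(sprintf("%s: missing 'rbe' column", path))
  parts <- split_person_column(df)
  v <- suppressWarnings(as.numeric(parts$data[["rbe"]]))
  if (anyNA(v) || !all(v %in% c(0, 1)))
    stop_format(sprintf("%s: 'rbe' values must be 0 or 1", path))
  stats::setNames(as.integer(v), parts$ids)
}

#' Write scored theta estimates to CSV
#'
#' Columns `person,theta,se,method,model,correction,converged,n_iter,at_boundary`
#' with `theta` and `se` printed at 4 decimals.
#'
#' @param x A `theta_estimates` data frame from [score_sample()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_theta_estimates <- function(x, path) {
  out <- as.data.frame(x)
  out$theta <- sprintf("%.4f", out$theta)
  out$se <- ifelse(is.na(x$se), "", sprintf("%.4f", x$se))
  out$theta[is.na(x$theta)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an effort profile to CSV
#'
#' One row per person: identifier, per-item `sb` flags, `rte`, `rbe`.
#'
#' @param x An [effort_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effort_profile <- function(x, path) {
  sb <- x$sb
  cols <- if (!is.null(colnames(sb))) colnames(sb) else paste0("I", seq_len(ncol(sb)))
  ids <- if (!is.null(rownames(sb))) rownames(sb) else as.character(seq_len(nrow(sb)))
  out <- data.frame(person = ids, sb, rte = sprintf("%.4f", x$rte), rbe = x$rbe,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("person", paste0("sb_", cols), "rte", "rbe")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Writes `responses.csv`, `times.csv`, `truth.csv` (true theta and rbe per
#' person) and `design.yaml` (the design, minus the item table, which goes
#' to `items.csv`).
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  if (!inherits(sim, "simulated_dataset")) stop_invalid("'sim' must be a simulated_dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- rownames(sim$responses)
  resp <- data.frame(person = ids, sim$responses, check.names = FALSE)
  utils::write.csv(resp, file.path(dir, "responses.csv"), row.names = FALSE, quote = FALSE)
  tim <- data.frame(person = ids, round(sim$times, 6), check.names = FALSE)
  utils::write.csv(tim, file.path(dir, "times.csv"), row.names = FALSE, quote = FALSE)
  truth <- data.frame(person = ids, true_theta = sprintf("%.6f", sim$true_theta),
                      rbe = sim$true_rbe)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE, quote = FALSE)
  it <- as.data.frame(sim$design$items)
  utils::write.csv(it, file.path(dir, "items.csv"), row.names = FALSE, quote = FALSE)
  dsn <- sim$design
  dsn$items <- NULL
  yaml::write_yaml(unclass(dsn), file.path(dir, "design.yaml"))
  invisible(dir)
}

#' Run configuration for batch scoring
#'
#' Bundles and validates everything a scoring run needs: file paths, the
#' estimation method, the response-model variant, the guessing/correction
#' settings, the prior, and the effort-flagging parameters.
#'
#' @param items Path to the item parameter CSV (required).
#' @param responses Path to the response matrix CSV (required).
#' @param out Path for the scored output CSV (required).
#' @param method `"mle"` or `"bme"`.
#' @param variant Response-model variant, see [model_prob()].
#' @param times Optional path to a response-time CSV; enables effort
#'   flagging.
#' @param rbe Optional path to a per-person rapid/effortful CSV; overrides
#'   time-based classification.
#' @param n_options Number of response options.
#' @param correction `"none"`, `"random"` or `"ability"`.
#' @param k Ability-guessing slope for the correction and the
#'   informed-guessing model.
#' @param prior_mean,prior_sd Normal prior (BME).
#' @param percentile Response-time percentile for rapid flagging.
#' @param rte_cutoff RTE cutoff for rapid/effortful classification.
#' @param seed Integer seed recorded with the run.
#' @param log_level `"quiet"` or `"verbose"` (per-person diagnostics).
#' @return A list of class `run_config`.
#' @export
run_config <- function(items, responses, out,
                       method = c("mle", "bme"), variant = "2pl",
                       times = NULL, rbe = NULL, n_options = 4L,
                       correction = c("none", "random", "ability"), k = 0.228,
                       prior_mean = 0, prior_sd = 1, percentile = 10,
                       rte_cutoff = 0.90, seed = 1L,
                       log_level = c("quiet", "verbose")) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  log_level <- match.arg(log_level)
  check_model(variant)
  for (p in c(items, responses))
    if (!file.exists(p)) stop_invalid(sprintf("input file not found: %s", p))
  structure(list(items = items, responses = responses, out = out,
                 method = method, variant = variant, times = times, rbe = rbe,
                 n_options = n_options, correction = correction, k = k,
                 prior_mean = prior_mean, prior_sd = prior_sd,
                 percentile = percentile, rte_cutoff = rte_cutoff,
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

#' Execute a batch scoring run
#'
#' Orchestrates a full run from files to files: read item parameters and
#' responses, derive an effort profile from response times and/or an
#' explicit rapid/effortful vector if supplied, score every person, apply
#' the configured rapid-responder correction, and write the scored CSV.
#' Every configuration field is logged. Conformability mismatches between
#' input files are fatal diagnostics naming both files; requesting a
#' correction without any source of rapid/effortful classification is
#' fatal too.
#'
#' @param cfg A [run_config()].
#' @return The scored `theta_estimates` data frame, invisibly (also
#'   written to `cfg$out`).
#' @export
run_score_command <- function(cfg) {
  if (!inherits(cfg, "run_config")) stop_invalid("'cfg' must be a run_config")
  log_fn <- if (cfg$log_level == "verbose") message else function(...) invisible(NULL)
  for (f in names(unclass(cfg)))
    log_fn(sprintf("config %s = %s", f,
                   if (is.null(cfg[[f]])) "<unset>" else paste(cfg[[f]], collapse = ",")))
  items <- read_item_parameters(cfg$items)
  responses <- read_responses(cfg$responses)
  if (ncol(responses) != nrow(items))
    stop_invalid(sprintf(
      "'%s' has %d item columns but '%s' defines %d items",
      cfg$responses, ncol(responses), cfg$items, nrow(items)))

  effort <- NULL
  if (!is.null(cfg$times)) {
    rt <- read_response_times(cfg$times)
    if (!all(dim(rt) == dim(responses)))
      stop_invalid(sprintf("'%s' (%d x %d) does not match '%s' (%d x %d)",
                           cfg$times, nrow(rt), ncol(rt),
                           cfg$responses, nrow(responses), ncol(responses)))
    effort <- effort_profile(rt, percentile = cfg$percentile, cutoff = cfg$rte_cutoff)
  }
  if (!is.null(cfg$rbe)) {
    rbe <- read_rbe(cfg$rbe)
    if (length(rbe) != nrow(responses))
      stop_invalid(sprintf("'%s' has %d persons but '%s' has %d",
                           cfg$rbe, length(rbe), cfg$responses, nrow(responses)))
    if (is.null(effort)) {
      # explicit classification, all responses presumed solution behavior
      effort <- effort_profile(sb = matrix(1L, nrow(responses), ncol(responses)))
    }
    effort$rbe <- unname(rbe)
  }
  if (cfg$correction != "none" && is.null(effort))
    stop_invalid(sprintf(
      "correction '%s' requested but neither a times file nor an rbe file was supplied",
      cfg$correction))

  gcfg <- guessing_config(cfg$n_options,
                          switch(cfg$correction, none = "none",
                                 random = "random_guessing", ability = "ability_based"),
                          k = cfg$k)
  set.seed(cfg$seed)
  est <- score_sample(responses, items,
                      method = toupper(cfg$method), model = cfg$variant,
                      effort = effort, cfg = gcfg,
                      prior = prior_spec(cfg$prior_mean, cfg$prior_sd),
                      verbose = cfg$log_level == "verbose")
  est$person <- rownames(responses)
  write_theta_estimates(est, cfg$out)
  log_fn(sprintf("wrote %d scored person(s) to %s", nrow(est), cfg$out))
  invisible(est)
}
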