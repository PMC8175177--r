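# File formats and the reproducible-run dispatcher.
#
# Samples travel as CSV with a `time` column and optional `removals`
# column; schemes as JSON objects {n, m, removals}; every result document
# embeds the config, seed and an MD5 hash of the input data.

#' Read a progressively censored sample from CSV
#'
#' Accepts either a two-column file (`time`, `removals`), from which the
#' scheme is reconstructed (`n = m + sum(removals)`), or a one-column file
#' (`time`) together with an explicit `scheme` argument.  All
#' [censored_sample] invariants are validated.
#'
#' @param path CSV file path.
#' @param scheme Optional [progressive_scheme]; required for one-column
#'   input, and cross-checked against the `removals` column otherwise.
#' @return A [censored_sample].
#' @export
read_sample <- function(path, scheme = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stop(sprintf("could not parse '%s' as CSV: %s", path, conditionMessage(e)),
         call. = FALSE))
  if (nrow(df) == 0L) stop(sprintf("'%s' contains no observations", path), call. = FALSE)
  if (!"time" %in% names(df))
    stop(sprintf("'%s' must have a 'time' column", path), call. = FALSE)
  times <- df$time
  if (anyNA(times) || any(!is.finite(times)) || any(times <= 0))
    stop("'time' column must be finite and strictly positive", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("'time' column must be strictly increasing", call. = FALSE)
  if ("removals" %in% names(df)) {
    file_scheme <- progressive_scheme(nrow(df) + sum(df$removals), nrow(df),
                                      df$removals)
    if (!is.null(scheme)) {
      if (!identical(unclass(scheme), unclass(file_scheme)))
        stop("'scheme' disagrees with the removals column in the file",
             call. = FALSE)
    }
    scheme <- file_scheme
  } else if (is.null(scheme)) {
    stop("one-column input needs an explicit 'scheme'", call. = FALSE)
  }
  censored_sample(times, scheme)
}

#' Write a progressively censored sample to CSV
#'
#' Two-column format (`time`, `removals`) that [read_sample] reads back
#' without loss.
#'
#' @param sample A [censored_sample].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample <- function(sample, path) {
  check_sample(sample)
  utils::write.csv(data.frame(time = sample$times,
                              removals = sample$scheme$removals),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write removal schemes as JSON
#'
#' Schemes are serialized as a JSON object with fields `n`, `m`,
#' `removals`.
#'
#' @param scheme A [progressive_scheme].
#' @param path JSON file path.
#' @return `read_scheme` returns a [progressive_scheme]; `write_scheme`
#'   returns `path` invisibly.
#' @export
write_scheme <- function(scheme, path) {
  if (!inherits(scheme, "wfr_scheme"))
    stop("'scheme' must be a progressive_scheme", call. = FALSE)
  jsonlite::write_json(list(n = scheme$n, m = scheme$m,
                            removals = scheme$removals),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  progressive_scheme(obj$n, obj$m, obj$removals)
}

resolve_data <- function(config) {
  data <- config$data
  if (is.null(data)) stop("config needs a 'data' entry", call. = FALSE)
  if (identical(data, "gastric")) {
    path <- system.file("extdata", "gastric_cancer.csv", package = "wfrcens",
                        mustWork = TRUE)
    x <- gastric_cancer()
    scheme <- progressive_scheme(length(x), length(x), rep(0L, length(x)))
    sample <- censored_sample(x, scheme)
  } else if (identical(data, "simulated")) {
    path <- system.file("extdata", "simulated_censored.csv",
                        package = "wfrcens", mustWork = TRUE)
    sample <- simulated_example()
  } else {
    path <- data
    scheme <- if (!is.null(config$scheme_file)) read_scheme(config$scheme_file)
              else if (!is.null(config$scheme))
                progressive_scheme(config$scheme$n, config$scheme$m,
                                   config$scheme$removals)
              else NULL
    sample <- read_sample(path, scheme)
  }
  list(sample = sample, hash = unname(tools::md5sum(path)))
}

config_params <- function(config, name) {
  v <- config[[name]]
  if (is.null(v)) NULL else as_wfr_params(unlist(v))
}

#' Run a self-describing analysis from a configuration
#'
#' Dispatches one of the commands `fit`, `bootstrap`, `bayes`, `simulate`,
#' `study` or `gof` to the corresponding package function and (optionally)
#' writes a JSON result document embedding the configuration, the seed and
#' an MD5 hash of the input data, so that a run can be reproduced exactly
#' from its own output.
#'
#' Config fields (list or path to a JSON file): `command`; `data` (CSV path
#' or fixture name `"gastric"` / `"simulated"`); `scheme` or `scheme_file`
#' for one-column data; `seed`; `output` (JSON path); and per-command
#' options (`level`, `t_eval`, `method`, `n_boot`, `n_total`, `burn_in`,
#' `prior_shape`, `prior_rate`, `init`, `estimates`, `params`, `truth`,
#' `designs`, `replicates`).  `simulate` draws from `params` under the
#' scheme of `data` (or an explicit `scheme`) and stores the sample.
#'
#' @param config A list or a path to a JSON config file.
#' @return The result document (list), invisibly when written to file.
#' @export
wfr_run <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  command <- match.arg(config$command,
                       c("fit", "bootstrap", "bayes", "simulate", "study", "gof"))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  level <- if (is.null(config$level)) 0.95 else config$level
  t_eval <- if (is.null(config$t_eval)) 0.5 else config$t_eval
  result <- switch(command,
    fit = {
      inp <- resolve_data(config)
      fit <- wfr_fit(inp$sample, init = config_params(config, "init"),
                     estimates = config_params(config, "estimates"))
      doc <- list(estimates = as.list(unclass(fit$estimates)),
                  loglik = fit$loglik, converged = fit$converged,
                  iterations = fit$iterations, score_norm = fit$score_norm,
                  vcov = fit$vcov)
      if (fit$converged || fit$fixed)
        doc$intervals <- tryCatch(wfr_asymptotic_ci(fit, level, t_eval),
                                  error = function(e) NULL)
      c(doc, list(data_hash = inp$hash))
    },
    bootstrap = {
      inp <- resolve_data(config)
      fit <- wfr_fit(inp$sample, estimates = config_params(config, "estimates"))
      method <- if (is.null(config$method)) "p" else config$method
      n_boot <- if (is.null(config$n_boot)) 1000 else config$n_boot
      bt <- wfr_boot(inp$sample, fit, method = method, n_boot = n_boot,
                     level = level, t_eval = t_eval)
      list(method = bt$method, n_boot = bt$n_boot, n_kept = bt$n_kept,
           dropped = bt$dropped, intervals = bt$intervals,
           data_hash = inp$hash)
    },
    bayes = {
      inp <- resolve_data(config)
      prior <- wfr_prior(shape = if (is.null(config$prior_shape)) 1e-4 else unlist(config$prior_shape),
                         rate = if (is.null(config$prior_rate)) 1e-4 else unlist(config$prior_rate))
      ch <- wfr_mcmc(inp$sample, prior = prior,
                     n_total = if (is.null(config$n_total)) 11000 else config$n_total,
                     burn_in = if (is.null(config$burn_in)) 1000 else config$burn_in,
                     init = config_params(config, "init"),
                     proposal_sd = config$proposal_sd, t_eval = t_eval)
      list(acceptance = as.list(ch$acceptance),
           summaries = lapply(as.data.frame(ch$draws), posterior_summaries),
           credible = lapply(as.data.frame(ch$draws), credible_interval,
                             level = level),
           data_hash = inp$hash)
    },
    simulate = {
      params <- config_params(config, "params")
      if (is.null(params)) stop("'simulate' needs 'params'", call. = FALSE)
      scheme <- if (!is.null(config$scheme))
        progressive_scheme(config$scheme$n, config$scheme$m, config$scheme$removals)
      else resolve_data(config)$sample$scheme
      smp <- rwfr_progressive(params, scheme)
      list(times = smp$times,
           scheme = list(n = scheme$n, m = scheme$m, removals = scheme$removals))
    },
    study = {
      truth <- config_params(config, "truth")
      if (is.null(truth)) stop("'study' needs 'truth'", call. = FALSE)
      designs <- as.data.frame(config$designs)
      st <- wfr_study(truth, designs = designs,
                      replicates = if (is.null(config$replicates)) 200 else config$replicates,
                      methods = if (is.null(config$methods)) "mle" else unlist(config$methods),
                      t_eval = t_eval, seed = seed)
      list(mse = st$mse, failed = st$failed)
    },
    gof = {
      inp <- resolve_data(config)
      x <- inp$sample$times
      fit <- if (!is.null(config$params))
        list(estimates = config_params(config, "params"))
      else wfr_fit(inp$sample)
      D <- ks_statistic(x, fit$estimates)
      list(estimates = as.list(unclass(fit$estimates)),
           ks_statistic = D, p_value = ks_pvalue(D, length(x)),
           data_hash = inp$hash)
    })
  doc <- list(command = command, seed = seed,
              package_version = as.character(utils::packageVersion("wfrcens")),
              config = config[setdiff(names(config), "output")],
              result = result)
  if (!is.null(config$output)) {
    jsonlite::write_json(doc, config$output, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    return(invisible(doc))
  }
  doc
}
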