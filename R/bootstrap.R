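# Parametric percentile (boot-p) and studentized (boot-t) bootstrap
# intervals for psi = (a, b, alpha, beta, r(t), h(t)).

quantity_names <- c("a", "b", "alpha", "beta", "r", "h")

# psi vector at given parameters
psi_vector <- function(th, t_eval) {
  c(unclass(th), r = wfr_reliability(t_eval, th), h = wfr_hazard(t_eval, th))
}

# delta-method standard errors of all six quantities from a fit
psi_se <- function(fit, t_eval) {
  B <- wfr_rh_grad(fit$estimates, t_eval)
  vr <- drop(t(B[, "r"]) %*% fit$vcov %*% B[, "r"])
  vh <- drop(t(B[, "h"]) %*% fit$vcov %*% B[, "h"])
  se <- sqrt(c(diag(fit$vcov), vr, vh))
  names(se) <- quantity_names
  se
}

# nearest-rank order statistic indices for a (1 - delta) interval on n values
rank_indices <- function(n, level) {
  delta <- 1 - level
  lo <- min(max(ceiling(n * delta / 2), 1L), n)
  hi <- min(max(ceiling(n * (1 - delta / 2)), 1L), n)
  c(lo, hi)
}

# percentile interval: order statistics of the replicate column
boot_interval_p <- function(column, level) {
  s <- sort(column)
  idx <- rank_indices(length(s), level)
  c(lower = s[idx[1]], upper = s[idx[2]])
}

# studentized interval: psi_hat + se_hat * T*_(k) with T* = (psi* - psi_hat)/se*
boot_interval_t <- function(psi_hat, se_hat, psi_star, se_star, level) {
  tstat <- sort((psi_star - psi_hat) / se_star)
  idx <- rank_indices(length(tstat), level)
  c(lower = psi_hat + se_hat * tstat[idx[1]],
    upper = psi_hat + se_hat * tstat[idx[2]])
}

#' Parametric bootstrap confidence intervals
#'
#' Both methods regenerate progressively censored samples from the fitted
#' parameters under the original removal scheme, refit each one (seeded at
#' the original estimates), and form intervals for all six quantities
#' \eqn{\psi = (a, b, \alpha, \beta, r(t), h(t))}.
#'
#' `method = "p"` (percentile): the interval endpoints are the
#' nearest-rank order statistics of the sorted replicate values at
#' probabilities \eqn{\delta/2} and \eqn{1 - \delta/2}.
#'
#' `method = "t"` (studentized): each replicate contributes
#' \eqn{T^* = (\hat\psi^* - \hat\psi)/\sqrt{\widehat{var}(\hat\psi^*)}} with
#' the replicate variance from its observed-information inverse (delta
#' method for `r` and `h`); the interval is
#' \eqn{\hat\psi + \widehat{se}(\hat\psi)\, T^*_{(k)}} at the same ranks.
#'
#' Each replicate uses the constrained maximizer of its own likelihood:
#' because the WFr likelihood can be too flat for a certified stationary
#' point on every resample, a refit is kept whenever it ends strictly
#' inside the search box (for boot-t it must also yield finite, positive
#' replicate variances).  Refits that error out or end on the box boundary
#' are dropped and counted; more than 20% drops is an error.  Uses the current R random stream unless `seed` is given.
#'
#' @param sample A [censored_sample].
#' @param fit The corresponding converged [wfr_fit] (or an evaluation at
#'   fixed estimates).
#' @param method `"p"` (percentile) or `"t"` (studentized).
#' @param n_boot Number of bootstrap replicates.
#' @param level Confidence level.
#' @param t_eval Evaluation time for reliability and hazard.
#' @param seed Optional integer seed.
#' @return An object of class `wfr_boot`: list with `replicates`
#'   (kept replicates x 6 matrix), `replicate_se` (boot-t only),
#'   `intervals` (data frame), `method`, `n_boot`, `n_kept`, `dropped`,
#'   `level`, `t_eval`, `seed`.
#' @export
wfr_boot <- function(sample, fit, method = c("p", "t"), n_boot = 1000,
                     level = 0.95, t_eval = 0.5, seed = NULL) {
  check_sample(sample)
  method <- match.arg(method)
  check_ci_ready(fit)
  if (!is.null(seed)) set.seed(seed)
  n_boot <- as.integer(n_boot)
  stopifnot(n_boot >= 2)
  th_hat <- fit$estimates
  psi_hat <- psi_vector(th_hat, t_eval)
  reps <- matrix(NA_real_, n_boot, 6, dimnames = list(NULL, quantity_names))
  rep_se <- if (method == "t")
    matrix(NA_real_, n_boot, 6, dimnames = list(NULL, quantity_names)) else NULL
  keep <- logical(n_boot)
  for (i in seq_len(n_boot)) {
    star <- rwfr_progressive(th_hat, sample$scheme)
    refit <- tryCatch(suppressWarnings(wfr_fit(star, init = th_hat)),
                      error = function(e) NULL)
    if (is.null(refit) || !isTRUE(refit$interior)) next
    reps[i, ] <- psi_vector(refit$estimates, t_eval)
    if (method == "t") {
      se <- tryCatch(suppressWarnings(psi_se(refit, t_eval)),
                     error = function(e) NULL)
      if (is.null(se) || any(!is.finite(se)) || any(se <= 0)) next
      rep_se[i, ] <- se
    }
    keep[i] <- TRUE
  }
  dropped <- n_boot - sum(keep)
  if (dropped > 0.2 * n_boot)
    stop(sprintf("%d of %d bootstrap refits failed (> 20%%)", dropped, n_boot),
         call. = FALSE)
  reps <- reps[keep, , drop = FALSE]
  if (method == "t") rep_se <- rep_se[keep, , drop = FALSE]
  intervals <- if (method == "p") {
    t(apply(reps, 2, boot_interval_p, level = level))
  } else {
    se_hat <- suppressWarnings(psi_se(fit, t_eval))
    t(vapply(quantity_names, function(qn)
      boot_interval_t(psi_hat[qn], se_hat[qn], reps[, qn], rep_se[, qn], level),
      numeric(2)))
  }
  intervals <- data.frame(quantity = quantity_names,
                          estimate = unname(psi_hat),
                          lower = intervals[, 1], upper = intervals[, 2],
                          row.names = NULL)
  structure(list(replicates = reps, replicate_se = rep_se,
                 intervals = intervals, method = paste0("boot-", method),
                 n_boot = n_boot, n_kept = sum(keep), dropped = dropped,
                 level = level, t_eval = t_eval, seed = seed),
            class = "wfr_boot")
}

#' @export
print.wfr_boot <- function(x, ...) {
  cat(sprintf("%s intervals (%d%% level, %d/%d replicates kept)\n",
              x$method, round(100 * x$level), x$n_kept, x$n_boot))
  print(x$intervals, ...)
  invisible(x)
}
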