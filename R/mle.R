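# Censored log-likelihood, analytic score, profile MLE of a, Newton-type
# fitting, observed information, asymptotic and delta-method intervals.
#
# Throughout, x_k = (alpha / y_k)^beta, g_k = exp(x_k) - 1, and the censored
# log-likelihood (up to the scheme-dependent additive constant) is
#   l = m log a + m log b + m log beta + m beta log alpha
#       - (beta + 1) sum log y_k - b sum x_k
#       - a sum (R_k + 1) g_k^{-b} - (b + 1) sum log(1 - e^{-x_k}).

check_sample <- function(sample) {
  if (!inherits(sample, "wfr_sample"))
    stop("'sample' must be a censored_sample", call. = FALSE)
  invisible(sample)
}

#' Censored Weibull-Frechet log-likelihood
#'
#' Log-likelihood of a progressively type-II censored sample, omitting the
#' scheme-dependent additive constant.  Each observed failure contributes its
#' log-density plus `removals[k]` times the log-reliability at that time.
#'
#' @param params A [wfr_params] object.
#' @param sample A [censored_sample].
#' @return Scalar log-likelihood.
#' @export
wfr_loglik <- function(params, sample) {
  th <- as_wfr_params(params)
  check_sample(sample)
  y <- sample$times; R <- sample$scheme$removals; m <- length(y)
  x <- (th["alpha"] / y)^th["beta"]
  lg <- log_expm1(x)
  unname(m * log(th["a"]) + m * log(th["b"]) + m * log(th["beta"]) +
    m * th["beta"] * log(th["alpha"]) - (th["beta"] + 1) * sum(log(y)) -
    th["b"] * sum(x) -
    th["a"] * sum((R + 1) * exp(-th["b"] * lg)) -
    (th["b"] + 1) * sum(log1p(-exp(-x))))
}

#' Score vector of the censored log-likelihood
#'
#' Analytic gradient of [wfr_loglik] in the order
#' \eqn{(\partial_a, \partial_b, \partial_\alpha, \partial_\beta)}.
#'
#' @inheritParams wfr_loglik
#' @return Named numeric vector of length four.
#' @export
wfr_score <- function(params, sample) {
  th <- as_wfr_params(params)
  check_sample(sample)
  y <- sample$times; R <- sample$scheme$removals; m <- length(y)
  a <- th["a"]; b <- th["b"]; alpha <- th["alpha"]; beta <- th["beta"]
  x <- (alpha / y)^beta
  lg <- log_expm1(x)
  G <- exp(-b * lg)                     # (e^x - 1)^{-b}
  da <- m / a - sum((R + 1) * G)
  db <- m / b - sum(x) + a * sum((R + 1) * G * lg) - sum(log1p(-exp(-x)))
  # dl/dx_k, then chain through x = (alpha/y)^beta
  dldx <- -b + a * b * (R + 1) * exp(x - (b + 1) * lg) - (b + 1) * exp(-lg)
  dalpha <- m * beta / alpha + sum(dldx * beta * x / alpha)
  dbeta <- m / beta + m * log(alpha) - sum(log(y)) + sum(dldx * x * log(alpha / y))
  c(a = unname(da), b = unname(db), alpha = unname(dalpha), beta = unname(dbeta))
}

#' Profile maximum-likelihood estimate of a
#'
#' For fixed `(b, alpha, beta)` the score equation in `a` has the closed-form
#' solution
#' \deqn{\hat a = m \Big/ \sum_k (R_k + 1)\,(e^{x_k} - 1)^{-b},}
#' which is used to profile `a` out of the four-dimensional search.
#'
#' @param b,alpha,beta Positive scalars.
#' @inheritParams wfr_loglik
#' @return Positive scalar.
#' @export
wfr_profile_a <- function(b, alpha, beta, sample) {
  check_sample(sample)
  if (any(c(b, alpha, beta) <= 0) || anyNA(c(b, alpha, beta)))
    stop("b, alpha, beta must be strictly positive", call. = FALSE)
  y <- sample$times; R <- sample$scheme$removals
  x <- (alpha / y)^beta
  S <- sum((R + 1) * exp(-b * log_expm1(x)))
  if (!is.finite(S) || S <= 0)
    stop("profile denominator underflowed; (b, alpha, beta) too extreme for these data",
         call. = FALSE)
  length(y) / S
}

#' Observed Fisher information
#'
#' Negative Hessian of the censored log-likelihood, computed by central
#' differences of the analytic score (step `1e-5 * max(1, |theta|)`) and
#' symmetrized.
#'
#' @inheritParams wfr_loglik
#' @return Symmetric 4 x 4 matrix with dimnames `a`, `b`, `alpha`, `beta`.
#' @export
wfr_obs_info <- function(params, sample) {
  th <- as.numeric(as_wfr_params(params))
  check_sample(sample)
  H <- vapply(1:4, function(j) {
    h <- 1e-5 * max(1, abs(th[j]))
    tp <- th; tm <- th
    tp[j] <- th[j] + h; tm[j] <- th[j] - h
    (wfr_score(wfr_params(tp[1], tp[2], tp[3], tp[4]), sample) -
       wfr_score(wfr_params(tm[1], tm[2], tm[3], tm[4]), sample)) / (2 * h)
  }, numeric(4))
  I <- -(H + t(H)) / 2
  dimnames(I) <- list(c("a", "b", "alpha", "beta"), c("a", "b", "alpha", "beta"))
  I
}

#' Control settings for [wfr_fit]
#'
#' @param grad_tol Convergence criterion: sup-norm of the score below this.
#' @param max_iter Maximum optimizer iterations.
#' @param log_bound Half-width of the search box for `log(b)`, `log(alpha)`,
#'   `log(beta)` around zero; fits ending on the box boundary are flagged as
#'   non-converged.
#' @param grid Multipliers used to seed the optimizer: `b` and `beta` start
#'   from the grid values themselves, `alpha` from the grid values scaled by
#'   the sample median.
#' @return A list of class `wfr_fit_control`.
#' @export
wfr_fit_control <- function(grad_tol = 1e-8, max_iter = 500, log_bound = 7,
                            grid = c(0.5, 1, 2)) {
  stopifnot(grad_tol > 0, max_iter >= 1, log_bound > 0, all(grid > 0))
  structure(list(grad_tol = grad_tol, max_iter = max_iter,
                 log_bound = log_bound, grid = grid),
            class = "wfr_fit_control")
}

# negative profiled log-likelihood and gradient over p = log(b, alpha, beta)
profile_nll <- function(p, y, R, sample = NULL) {
  m <- length(y)
  b <- exp(p[1]); alpha <- exp(p[2]); beta <- exp(p[3])
  x <- (alpha / y)^beta
  lg <- log_expm1(x)
  S <- sum((R + 1) * exp(-b * lg))
  if (!is.finite(S) || S <= 0) return(1e10)
  a <- m / S
  v <- -(m * log(a) + m * log(b) + m * log(beta) + m * beta * log(alpha) -
           (beta + 1) * sum(log(y)) - b * sum(x) - m -
           (b + 1) * sum(log1p(-exp(-x))))
  if (is.finite(v)) v else 1e10
}

profile_nll_grad <- function(p, y, R, sample) {
  b <- exp(p[1]); alpha <- exp(p[2]); beta <- exp(p[3])
  a <- tryCatch(wfr_profile_a(b, alpha, beta, sample), error = function(e) NA)
  if (!is.finite(a)) return(c(0, 0, 0))
  s <- wfr_score(wfr_params(a, b, alpha, beta), sample)
  g <- -c(s[2] * b, s[3] * alpha, s[4] * beta)
  ifelse(is.finite(g), g, 0)
}

# damped Newton iterations on the profiled score in log coordinates
newton_polish <- function(lq, sample, tol, max_iter) {
  y <- sample$times
  ps <- function(lq) {
    q <- exp(lq)
    a <- wfr_profile_a(q[1], q[2], q[3], sample)
    wfr_score(wfr_params(a, q[1], q[2], q[3]), sample)[2:4] * q
  }
  iters <- 0L
  s <- tryCatch(ps(lq), error = function(e) rep(NA_real_, 3))
  if (!all(is.finite(s))) return(list(lq = lq, iterations = 0L))
  for (it in seq_len(max_iter)) {
    if (max(abs(s)) < tol / 10) break
    J <- tryCatch(vapply(1:3, function(j) {
      h <- 1e-6
      lp <- lq; lm <- lq
      lp[j] <- lq[j] + h; lm[j] <- lq[j] - h
      (ps(lp) - ps(lm)) / (2 * h)
    }, numeric(3)), error = function(e) NULL)
    if (is.null(J) || !all(is.finite(J))) break
    dq <- tryCatch(solve(J, -s), error = function(e) NULL)
    if (is.null(dq)) break
    step <- 1
    repeat {
      s2 <- tryCatch(ps(lq + step * dq), error = function(e) NA)
      if (all(is.finite(s2)) && sum(s2^2) < sum(s^2)) break
      step <- step / 2
      if (step < 1e-8) break
    }
    if (step < 1e-8) break
    lq <- lq + step * dq
    s <- ps(lq)
    iters <- it
  }
  list(lq = lq, iterations = iters)
}

#' Fit the Weibull-Frechet model to a progressively censored sample
#'
#' Maximum likelihood with `a` profiled out in closed form, reducing the
#' search to `(b, alpha, beta)`.  The optimizer works on the log scale
#' (enforcing positivity) inside a bounded box, seeded either from `init` or
#' from a coarse grid with `alpha` scaled by the sample median; the best box
#' point is refined by L-BFGS-B and then polished by damped Newton steps on
#' the analytic score.  The variance-covariance matrix is the inverse of the
#' observed information ([wfr_obs_info]).
#'
#' The WFr likelihood can be very flat in small samples and may increase
#' monotonically towards a degenerate boundary (`beta` tending to 0 with `b`
#' growing without bound); a fit that ends on the search-box boundary is
#' returned with `converged = FALSE` rather than as an error.
#'
#' Alternatively, supply `estimates` to skip optimization and evaluate the
#' likelihood, score, information and intervals at fixed parameter values
#' (e.g. published estimates).
#'
#' @param sample A [censored_sample].
#' @param init Optional [wfr_params] starting value (replaces the grid).
#' @param estimates Optional [wfr_params]; evaluate at these values instead
#'   of optimizing.
#' @param control A [wfr_fit_control] list.
#' @return An object of class `wfr_fit`: list with `estimates`
#'   ([wfr_params]), `loglik`, `vcov`, `converged`, `iterations`,
#'   `score_norm`, `fixed` (TRUE when `estimates` was supplied), `sample`.
#' @seealso [wfr_asymptotic_ci], [wfr_boot], [wfr_mcmc]
#' @export
wfr_fit <- function(sample, init = NULL, estimates = NULL,
                    control = wfr_fit_control()) {
  check_sample(sample)
  if (!inherits(control, "wfr_fit_control")) control <- do.call(wfr_fit_control, control)
  y <- sample$times; R <- sample$scheme$removals
  if (!is.null(estimates)) {
    th <- as_wfr_params(estimates)
    s <- wfr_score(th, sample)
    return(new_wfr_fit(th, sample, iterations = 0L, fixed = TRUE,
                       converged = max(abs(s)) < control$grad_tol,
                       score_norm = max(abs(s))))
  }
  bound <- control$log_bound
  grid_start <- function() {
    med <- stats::median(y)
    starts <- as.matrix(expand.grid(b = control$grid, alpha = control$grid * med,
                                    beta = control$grid))
    vals <- apply(starts, 1, function(q) profile_nll(log(q), y, R))
    log(starts[which.min(vals), ])
  }
  p0_list <- if (is.null(init)) list(grid_start())
             else list(log(as.numeric(as_wfr_params(init))[2:4]), grid_start())
  best <- NULL
  for (p0 in p0_list) {
    p0 <- pmin(pmax(p0, -bound), bound)
    opt <- stats::optim(p0, profile_nll, gr = profile_nll_grad,
                        y = y, R = R, sample = sample,
                        method = "L-BFGS-B", lower = -bound, upper = bound,
                        control = list(maxit = control$max_iter, factr = 1e4))
    pol <- newton_polish(opt$par, sample, control$grad_tol, 50L)
    lq <- pol$lq
    interior <- all(abs(lq) < bound - 1e-6)
    if (!interior) lq <- pmin(pmax(opt$par, -bound), bound)  # keep the boxed point
    cand <- list(lq = lq, interior = interior,
                 iterations = opt$counts[["function"]] + pol$iterations,
                 nll = profile_nll(lq, y, R))
    q <- exp(lq)
    cand$score_norm <- tryCatch({
      a <- wfr_profile_a(q[1], q[2], q[3], sample)
      max(abs(wfr_score(wfr_params(a, q[1], q[2], q[3]), sample)))
    }, error = function(e) Inf)
    # a certified optimum must be interior, stationary, and a local maximum
    # (positive-definite observed information); stationary saddle points are
    # rejected so that the next start gets a chance
    cand$ok <- cand$interior && cand$score_norm < control$grad_tol &&
      tryCatch({
        a <- wfr_profile_a(q[1], q[2], q[3], sample)
        min(eigen(wfr_obs_info(wfr_params(a, q[1], q[2], q[3]), sample),
                  symmetric = TRUE, only.values = TRUE)$values) > 0
      }, error = function(e) FALSE)
    if (is.null(best) || (cand$ok && !best$ok) ||
        (cand$ok == best$ok && cand$nll < best$nll)) best <- cand
    if (best$ok) break  # first start already certified
  }
  q <- exp(best$lq)
  a <- wfr_profile_a(q[1], q[2], q[3], sample)
  th <- wfr_params(a, q[1], q[2], q[3])
  new_wfr_fit(th, sample, iterations = best$iterations, fixed = FALSE,
              converged = best$ok, score_norm = best$score_norm,
              interior = best$interior)
}

new_wfr_fit <- function(th, sample, iterations, fixed, converged, score_norm,
                        interior = NA) {
  I <- wfr_obs_info(th, sample)
  V <- tryCatch(solve(I), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V))) {
    V <- matrix(NA_real_, 4, 4, dimnames = dimnames(I))
    warning("observed information is singular; variance-covariance set to NA",
            call. = FALSE)
  }

  structure(list(estimates = th, loglik = wfr_loglik(th, sample), vcov = V,
                 converged = converged, iterations = as.integer(iterations),
                 score_norm = unname(score_norm), fixed = fixed,
                 interior = interior, sample = sample),
            class = "wfr_fit")
}

#' @export
print.wfr_fit <- function(x, ...) {
  cat("Weibull-Frechet", if (x$fixed) "evaluation at fixed estimates"
      else "maximum-likelihood fit", "\n")
  cat(sprintf("  m = %d observed of n = %d\n", x$sample$scheme$m, x$sample$scheme$n))
  print(unclass(x$estimates))
  cat(sprintf("  log-likelihood %.4f | score sup-norm %.3g | converged: %s\n",
              x$loglik, x$score_norm, x$converged))
  invisible(x)
}

#' @export
coef.wfr_fit <- function(object, ...) unclass(object$estimates)

#' @export
vcov.wfr_fit <- function(object, ...) object$vcov

#' @export
logLik.wfr_fit <- function(object, ...) {
  structure(object$loglik, df = 4L, nobs = object$sample$scheme$m, class = "logLik")
}

#' Asymptotic-normal confidence intervals for the parameters
#'
#' Wald intervals `estimate +/- z_{delta/2} * sqrt(var)` from the inverse
#' observed information.  Bounds are reported untruncated: a lower bound may
#' be negative even though the parameters are positive.
#'
#' @param object A converged [wfr_fit].
#' @param parm Parameters to report (default all four).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Matrix with columns `lower`, `upper`.
#' @export
confint.wfr_fit <- function(object, parm = c("a", "b", "alpha", "beta"),
                            level = 0.95, ...) {
  check_ci_ready(object)
  parm <- match.arg(parm, several.ok = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- unclass(object$estimates)[parm]
  se <- sqrt(diag(object$vcov)[parm])
  cbind(lower = est - z * se, upper = est + z * se)
}

check_ci_ready <- function(fit) {
  if (!inherits(fit, "wfr_fit")) stop("'fit' must be a wfr_fit", call. = FALSE)
  if (!fit$fixed && !fit$converged)
    stop("fit did not converge; intervals are not available", call. = FALSE)
  if (any(!is.finite(fit$vcov)))
    stop("variance-covariance matrix is not available", call. = FALSE)
  invisible(fit)
}

#' Delta-method intervals for reliability and hazard
#'
#' Propagates the estimator covariance through \eqn{r(t)} and \eqn{h(t)}
#' using their analytic gradients ([wfr_rh_grad]):
#' \eqn{\mathrm{var}(\hat r) = B_1' \hat V B_1},
#' \eqn{\mathrm{var}(\hat h) = B_2' \hat V B_2}.  The upper reliability bound
#' may exceed 1 since no truncation is applied.
#'
#' @param fit A converged [wfr_fit].
#' @param t Positive evaluation time (default 0.5).
#' @param level Confidence level.
#' @return Matrix with rows `r`, `h` and columns `estimate`, `lower`, `upper`.
#' @export
wfr_delta_ci <- function(fit, t = 0.5, level = 0.95) {
  check_ci_ready(fit)
  th <- fit$estimates
  B <- wfr_rh_grad(th, t)
  vr <- drop(t(B[, "r"]) %*% fit$vcov %*% B[, "r"])
  vh <- drop(t(B[, "h"]) %*% fit$vcov %*% B[, "h"])
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- c(r = wfr_reliability(t, th), h = wfr_hazard(t, th))
  cbind(estimate = est,
        lower = est - z * sqrt(c(vr, vh)),
        upper = est + z * sqrt(c(vr, vh)))
}

#' All six asymptotic intervals
#'
#' Convenience wrapper returning the Wald intervals for the four parameters
#' together with the delta-method intervals for `r(t)` and `h(t)`.
#'
#' @inheritParams wfr_delta_ci
#' @param t_eval Positive evaluation time for reliability and hazard.
#' @return Data frame with columns `quantity`, `estimate`, `lower`, `upper`;
#'   attributes `level` and `t_eval`.
#' @export
wfr_asymptotic_ci <- function(fit, level = 0.95, t_eval = 0.5) {
  ci <- confint.wfr_fit(fit, level = level)
  dci <- wfr_delta_ci(fit, t = t_eval, level = level)
  out <- data.frame(quantity = c("a", "b", "alpha", "beta", "r", "h"),
                    estimate = c(unclass(fit$estimates), dci[, "estimate"]),
                    lower = c(ci[, "lower"], dci[, "lower"]),
                    upper = c(ci[, "upper"], dci[, "upper"]),
                    row.names = NULL)
  attr(out, "level") <- level
  attr(out, "t_eval") <- t_eval
  out
}
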