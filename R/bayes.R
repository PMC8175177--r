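# Gibbs-within-Metropolis-Hastings posterior sampling under independent
# gamma priors, credible intervals, posterior summaries, and balanced-loss
# point estimation.
#
# With independent Gamma(c_i, k_i) priors (shape/rate) on a, b, alpha, beta,
# the full conditional of a is Gamma(m + c1, k1 + sum (R_k+1) g_k^{-b}) and
# is sampled exactly; b, alpha and beta are updated by random-walk
# Metropolis-Hastings with normal proposals.

#' Independent gamma priors for the Weibull-Frechet parameters
#'
#' Shape/rate gamma priors for `a`, `b`, `alpha`, `beta` (in that order).
#' The default `1e-4` for every hyperparameter is proper but nearly flat.
#'
#' @param shape,rate Positive vectors of length 4 (recycled if length 1).
#' @return An object of class `wfr_prior`: list with `shape` and `rate`,
#'   each named `a`, `b`, `alpha`, `beta`.
#' @export
wfr_prior <- function(shape = 1e-4, rate = 1e-4) {
  shape <- rep_len(as.numeric(shape), 4L)
  rate <- rep_len(as.numeric(rate), 4L)
  if (anyNA(shape) || anyNA(rate) || any(shape <= 0) || any(rate <= 0))
    stop("all hyperparameters must be finite and strictly positive", call. = FALSE)
  names(shape) <- names(rate) <- c("a", "b", "alpha", "beta")
  structure(list(shape = shape, rate = rate), class = "wfr_prior")
}

#' Full conditional of a
#'
#' Given `(b, alpha, beta)` and the data, the conditional posterior of `a`
#' is gamma with shape `m + c1` and rate
#' `k1 + sum((R_k + 1) (exp(x_k) - 1)^(-b))`.
#'
#' @param b,alpha,beta Positive scalars (current values of the other
#'   parameters).
#' @param sample A [censored_sample].
#' @param prior A [wfr_prior].
#' @return List with elements `shape` and `rate`.
#' @export
wfr_conditional_a <- function(b, alpha, beta, sample, prior = wfr_prior()) {
  check_sample(sample)
  if (!inherits(prior, "wfr_prior")) stop("'prior' must be a wfr_prior", call. = FALSE)
  y <- sample$times; R <- sample$scheme$removals
  x <- (alpha / y)^beta
  S <- sum((R + 1) * exp(-b * log_expm1(x)))
  if (!is.finite(S) || S <= 0)
    stop("conditional rate underflowed; (b, alpha, beta) too extreme for these data",
         call. = FALSE)
  list(shape = length(y) + prior$shape[["a"]], rate = prior$rate[["a"]] + S)
}

# shared likelihood part of the b/alpha/beta conditionals:
# -b sum x - a sum (R+1) g^{-b} - (b+1) sum log(1 - e^{-x})
conditional_common <- function(a, b, alpha, beta, y, R) {
  x <- (alpha / y)^beta
  -b * sum(x) - a * sum((R + 1) * exp(-b * log_expm1(x))) -
    (b + 1) * sum(log1p(-exp(-x)))
}

#' Log conditional posterior kernels of b, alpha, beta
#'
#' Unnormalized log conditional posterior density of one of `b`, `alpha`,
#' `beta` given the other parameters, as used inside the
#' Metropolis-Hastings acceptance ratio.  Nonpositive `value` returns
#' `-Inf` (zero prior mass), which makes negative proposals auto-reject.
#'
#' @param which One of `"b"`, `"alpha"`, `"beta"`.
#' @param value Point at which to evaluate the kernel.
#' @param params A [wfr_params] holding the current values of all four
#'   parameters (the `which` entry is ignored in favour of `value`).
#' @param sample A [censored_sample].
#' @param prior A [wfr_prior].
#' @return Scalar log kernel (possibly `-Inf`).
#' @export
wfr_log_conditional <- function(which = c("b", "alpha", "beta"), value,
                                params, sample, prior = wfr_prior()) {
  which <- match.arg(which)
  check_sample(sample)
  if (!inherits(prior, "wfr_prior")) stop("'prior' must be a wfr_prior", call. = FALSE)
  if (length(value) != 1L || is.na(value)) stop("'value' must be a scalar", call. = FALSE)
  if (value <= 0) return(-Inf)
  th <- as_wfr_params(params)
  a <- th[["a"]]; b <- th[["b"]]; alpha <- th[["alpha"]]; beta <- th[["beta"]]
  y <- sample$times; R <- sample$scheme$removals; m <- length(y)
  switch(which,
    b = {
      b <- value
      (m + prior$shape[["b"]] - 1) * log(b) - prior$rate[["b"]] * b +
        conditional_common(a, b, alpha, beta, y, R)
    },
    alpha = {
      alpha <- value
      (m * beta + prior$shape[["alpha"]] - 1) * log(alpha) -
        prior$rate[["alpha"]] * alpha +
        conditional_common(a, b, alpha, beta, y, R)
    },
    beta = {
      beta <- value
      (m + prior$shape[["beta"]] - 1) * log(beta) -
        (beta + 1) * sum(log(y)) - prior$rate[["beta"]] * beta +
        conditional_common(a, b, alpha, beta, y, R)
    })
}

#' Gibbs-within-Metropolis-Hastings posterior sampler
#'
#' Each sweep draws `a` exactly from its gamma full conditional, then
#' updates `b`, `alpha` and `beta` in turn by random-walk
#' Metropolis-Hastings with normal proposals centred at the current values.
#' Every retained state is transformed to `r(t)` and `h(t)`.  The first
#' `burn_in` sweeps are discarded.
#'
#' Defaults follow common practice for this model: the chain is initialized
#' at the maximum-likelihood estimates and the proposal standard deviations
#' are the asymptotic standard errors of `(b, alpha, beta)` from the MLE
#' fit.  If no converged fit is available, supply `init` and `proposal_sd`
#' explicitly.  A proposal standard deviation of exactly 0 freezes that
#' block (useful for validating the exact `a`-step).  Uses the current R
#' random stream unless `seed` is given.
#'
#' @param sample A [censored_sample].
#' @param prior A [wfr_prior].
#' @param n_total Total sweeps N.
#' @param burn_in Discarded initial sweeps M (`0 <= M < N`).
#' @param init Optional [wfr_params] starting state.
#' @param proposal_sd Optional nonnegative length-3 vector of proposal
#'   standard deviations for `(b, alpha, beta)`.
#' @param t_eval Evaluation time for reliability and hazard.
#' @param fit Optional [wfr_fit] supplying defaults for `init` and
#'   `proposal_sd`.
#' @param seed Optional integer seed.
#' @return An object of class `wfr_mcmc`: list with `draws`
#'   ((N - M) x 6 matrix, columns `a`, `b`, `alpha`, `beta`, `r`, `h`),
#'   `acceptance` (named rates for `b`, `alpha`, `beta`), `n_total`,
#'   `burn_in`, `proposal_sd`, `init`, `t_eval`, `seed`.
#' @export
wfr_mcmc <- function(sample, prior = wfr_prior(), n_total = 11000,
                     burn_in = 1000, init = NULL, proposal_sd = NULL,
                     t_eval = 0.5, fit = NULL, seed = NULL) {
  check_sample(sample)
  if (!inherits(prior, "wfr_prior")) stop("'prior' must be a wfr_prior", call. = FALSE)
  n_total <- as.integer(n_total); burn_in <- as.integer(burn_in)
  if (n_total < 1L || burn_in < 0L || burn_in >= n_total)
    stop("need 0 <= burn_in < n_total", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init) || is.null(proposal_sd)) {
    if (is.null(fit)) fit <- wfr_fit(sample)
    if (is.null(init)) init <- fit$estimates
    if (is.null(proposal_sd)) {
      v <- diag(fit$vcov)[2:4]
      proposal_sd <- if (all(is.finite(v)) && all(v > 0)) sqrt(v)
                     else 0.1 * as.numeric(as_wfr_params(init))[2:4]
    }
  }
  th <- as.numeric(as_wfr_params(init))
  proposal_sd <- as.numeric(proposal_sd)
  if (length(proposal_sd) != 3L || anyNA(proposal_sd) || any(proposal_sd < 0))
    stop("'proposal_sd' must be three nonnegative values for (b, alpha, beta)",
         call. = FALSE)
  y <- sample$times; R <- sample$scheme$removals
  keep <- n_total - burn_in
  draws <- matrix(NA_real_, keep, 6,
                  dimnames = list(NULL, c("a", "b", "alpha", "beta", "r", "h")))
  accept <- c(b = 0, alpha = 0, beta = 0)
  blocks <- c("b", "alpha", "beta")
  a <- th[1]; b <- th[2]; alpha <- th[3]; beta <- th[4]
  for (k in seq_len(n_total)) {
    cond <- wfr_conditional_a(b, alpha, beta, sample, prior)
    a <- stats::rgamma(1L, shape = cond$shape, rate = cond$rate)
    cur <- c(b = b, alpha = alpha, beta = beta)
    for (j in 1:3) {
      par_now <- wfr_params(a, cur[["b"]], cur[["alpha"]], cur[["beta"]])
      prop <- stats::rnorm(1L, cur[[j]], proposal_sd[j])
      lr <- wfr_log_conditional(blocks[j], prop, par_now, sample, prior) -
        wfr_log_conditional(blocks[j], cur[[j]], par_now, sample, prior)
      if (is.finite(lr) && (lr >= 0 || log(stats::runif(1L)) < lr)) {
        cur[[j]] <- prop
        accept[j] <- accept[j] + 1
      } else if (proposal_sd[j] == 0) {
        # zero-scale proposal equals the current value; count as accepted
        accept[j] <- accept[j] + 1
      }
    }
    b <- cur[["b"]]; alpha <- cur[["alpha"]]; beta <- cur[["beta"]]
    if (k > burn_in) {
      st <- wfr_params(a, b, alpha, beta)
      draws[k - burn_in, ] <- c(a, b, alpha, beta,
                                wfr_reliability(t_eval, st),
                                wfr_hazard(t_eval, st))
    }
  }
  accept <- accept / n_total
  low <- accept < 0.01 & proposal_sd > 0
  if (any(low))
    warning(sprintf("acceptance below 1%% for: %s",
                    paste(blocks[low], collapse = ", ")), call. = FALSE)
  structure(list(draws = draws, acceptance = accept, n_total = n_total,
                 burn_in = burn_in, proposal_sd = proposal_sd,
                 init = as.numeric(th), t_eval = t_eval, seed = seed),
            class = "wfr_mcmc")
}

#' @export
print.wfr_mcmc <- function(x, ...) {
  cat(sprintf("MCMC: %d sweeps, %d retained; acceptance b %.2f, alpha %.2f, beta %.2f\n",
              x$n_total, nrow(x$draws), x$acceptance["b"], x$acceptance["alpha"],
              x$acceptance["beta"]))
  print(round(apply(x$draws, 2, stats::median), 4))
  invisible(x)
}

#' Equal-tail credible interval from posterior draws
#'
#' Nearest-rank order statistics of the sorted draws at probabilities
#' \eqn{\delta/2} and \eqn{1 - \delta/2} where \eqn{\delta} is
#' `1 - level`.
#'
#' @param draws Nonempty numeric vector.
#' @param level Credibility level in (0, 1).
#' @return Named vector `lower`, `upper`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  draws <- as.numeric(draws)
  if (length(draws) == 0L || anyNA(draws))
    stop("'draws' must be a nonempty numeric vector without NA", call. = FALSE)
  s <- sort(draws)
  idx <- rank_indices(length(s), level)
  c(lower = s[idx[1]], upper = s[idx[2]])
}

#' Balanced-loss Bayes point estimates
#'
#' Under balanced squared-error loss (BSEL) the estimate is
#' \eqn{w\,\hat\psi + (1-w)\,\bar\psi} with \eqn{\bar\psi} the posterior
#' mean; under balanced LINEX (BLINEX) it is
#' \eqn{-(1/q)\log\{w\,e^{-q\hat\psi} + (1-w)\,\overline{e^{-q\psi}}\}},
#' with the exponential average computed by log-sum-exp so that large
#' \eqn{|q\psi|} never overflows.  `w = 1` returns the frequentist estimate
#' exactly for both losses; BLINEX tends to BSEL as `q` tends to 0.
#'
#' @param draws Posterior draws of the quantity.
#' @param mle The frequentist (maximum-likelihood) estimate \eqn{\hat\psi}.
#' @param loss `"bsel"` or `"blinex"`.
#' @param w Mixing weight in `[0, 1]` on the frequentist estimate.
#' @param q Nonzero LINEX asymmetry parameter (BLINEX only).
#' @return Scalar point estimate.
#' @export
bayes_estimate <- function(draws, mle, loss = c("bsel", "blinex"), w = 0,
                           q = NULL) {
  loss <- match.arg(loss)
  draws <- as.numeric(draws)
  if (length(draws) == 0L || anyNA(draws)) stop("'draws' must be nonempty", call. = FALSE)
  if (length(w) != 1L || is.na(w) || w < 0 || w > 1)
    stop("'w' must lie in [0, 1]", call. = FALSE)
  if (loss == "bsel") return(w * mle + (1 - w) * mean(draws))
  if (is.null(q) || length(q) != 1L || is.na(q) || q == 0)
    stop("BLINEX requires a nonzero 'q'", call. = FALSE)
  # log of w e^{-q mle} + (1-w) mean(e^{-q draws}), all in log space
  terms <- c(if (w > 0) log(w) - q * mle,
             if (w < 1) log1p(-w) + log_mean_exp(-q * draws))
  -log_sum_exp(terms) / q
}

log_sum_exp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))

#' Posterior summary statistics
#'
#' Mean, median, mode, variance, standard deviation and skewness of a set
#' of draws.  Variance and skewness use the sample (n - 1 denominator,
#' adjusted Fisher-Pearson) conventions; the mode is the argmax of a
#' Gaussian kernel density estimate with Silverman's rule-of-thumb
#' bandwidth.
#'
#' @param draws Numeric vector with at least 3 values.
#' @return Named vector `mean`, `median`, `mode`, `variance`, `sd`,
#'   `skewness`.
#' @export
posterior_summaries <- function(draws) {
  draws <- as.numeric(draws)
  n <- length(draws)
  if (n < 3L || anyNA(draws))
    stop("'draws' must contain at least 3 non-NA values", call. = FALSE)
  v <- stats::var(draws)
  mode <- if (v == 0) draws[1] else {
    d <- stats::density(draws)
    d$x[which.max(d$y)]
  }
  skew <- if (v == 0) 0 else {
    z <- (draws - mean(draws)) / stats::sd(draws)
    n / ((n - 1) * (n - 2)) * sum(z^3)
  }
  c(mean = mean(draws), median = stats::median(draws), mode = mode,
    variance = v, sd = sqrt(v), skewness = skew)
}
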