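# Weibull-Frechet distribution: density, distribution, quantile, random
# variates, reliability and hazard.  All heavy exponentials are evaluated in
# log space so that (alpha/y)^beta up to several hundred stays finite.

#' Weibull-Frechet parameter set
#'
#' Bundles the four parameters of the Weibull-Frechet (WFr) distribution and
#' validates them.  `a`, `b` and `beta` are shape parameters; `alpha` is a
#' scale parameter in the same units as the observation time.  All four must
#' be finite and strictly positive.
#'
#' @param a,b,alpha,beta Positive scalars.
#' @return An object of class `wfr_params`: a named numeric vector of length
#'   four in the order `a`, `b`, `alpha`, `beta`.
#' @examples
#' wfr_params(0.5, 2.5, 0.96, 0.6)
#' @export
wfr_params <- function(a, b, alpha, beta) {
  v <- c(a = as.numeric(a)[1], b = as.numeric(b)[1],
         alpha = as.numeric(alpha)[1], beta = as.numeric(beta)[1])
  if (anyNA(v) || any(!is.finite(v)) || any(v <= 0))
    stop("all four parameters (a, b, alpha, beta) must be finite and strictly positive",
         call. = FALSE)
  structure(v, class = "wfr_params")
}

#' @export
print.wfr_params <- function(x, ...) {
  cat("Weibull-Frechet parameters:\n")
  print(unclass(x), ...)
  invisible(x)
}

as_wfr_params <- function(x) {
  if (inherits(x, "wfr_params")) return(x)
  x <- as.numeric(x)
  if (length(x) != 4L)
    stop("expected a wfr_params object or a numeric vector (a, b, alpha, beta)",
         call. = FALSE)
  wfr_params(x[1], x[2], x[3], x[4])
}

# log(exp(x) - 1) without overflow; x must be positive
log_expm1 <- function(x) ifelse(x > 30, x, log(expm1(x)))

check_positive_times <- function(y, what = "y") {
  if (length(y) == 0L || anyNA(y) || any(!is.finite(y)) || any(y <= 0))
    stop(sprintf("'%s' must contain finite, strictly positive values", what),
         call. = FALSE)
  invisible(y)
}

#' Weibull-Frechet distribution functions
#'
#' Density, distribution function, quantile function, random generation,
#' reliability (survival) and hazard rate for the four-parameter
#' Weibull-Frechet distribution.  Writing \eqn{x = (\alpha/y)^\beta}, the
#' survival function is \eqn{r(y) = \exp\{-a(e^{x} - 1)^{-b}\}} and the
#' density is the product of the hazard
#' \eqn{h(y) = ab\beta\alpha^\beta y^{-\beta-1} e^{-bx}(1 - e^{-x})^{-b-1}}
#' with the survival function.
#'
#' All terms of the form \eqn{(e^{x}-1)^{-b}} are computed as
#' \eqn{\exp\{-b(x + \log(1 - e^{-x}))\}}, so the functions return finite
#' values even when \eqn{x} is large enough that \eqn{e^{x}} would overflow.
#'
#' The quantile function inverts the distribution function in closed form:
#' \deqn{Q(u) = \alpha\,[\log(1 + (-\log(1-u)/a)^{-1/b})]^{-1/\beta}.}
#'
#' @param x,q Vector of positive times.
#' @param p Vector of probabilities in (0, 1).
#' @param n Number of draws.
#' @param t Vector of positive times at which to evaluate reliability/hazard.
#' @param params A [wfr_params] object (or numeric vector a, b, alpha, beta).
#' @param log,log.p Logical; return log values.
#' @param lower.tail Logical; if `FALSE`, `pwfr` returns the upper tail.
#' @return Numeric vector.
#' @examples
#' p <- wfr_params(0.5, 2.5, 0.96, 0.6)
#' pwfr(qwfr(0.3, p), p)
#' wfr_hazard(0.5, p) * wfr_reliability(0.5, p) - dwfr(0.5, p)
#' @name wfr-distribution
NULL

#' @rdname wfr-distribution
#' @export
dwfr <- function(x, params, log = FALSE) {
  th <- as_wfr_params(params)
  check_positive_times(x, "x")
  xx <- (th["alpha"] / x)^th["beta"]
  logf <- wfr_log_hazard_core(x, xx, th) - exp(log(th["a"]) - th["b"] * log_expm1(xx))
  logf <- unname(logf)
  if (log) logf else exp(logf)
}

# log h(y) given y and xx = (alpha/y)^beta
wfr_log_hazard_core <- function(y, xx, th) {
  log(th["a"]) + log(th["b"]) + log(th["beta"]) + th["beta"] * log(th["alpha"]) -
    (th["beta"] + 1) * log(y) - th["b"] * xx -
    (th["b"] + 1) * log1p(-exp(-xx))
}

#' @rdname wfr-distribution
#' @export
pwfr <- function(q, params, lower.tail = TRUE, log.p = FALSE) {
  th <- as_wfr_params(params)
  check_positive_times(q, "q")
  xx <- (th["alpha"] / q)^th["beta"]
  # u = a (e^xx - 1)^{-b};  S = exp(-u);  F = 1 - S
  u <- exp(log(th["a"]) - th["b"] * log_expm1(xx))
  res <- if (lower.tail) {
    if (log.p) log(-expm1(-u)) else -expm1(-u)
  } else {
    if (log.p) -u else exp(-u)
  }
  unname(res)
}

#' @rdname wfr-distribution
#' @export
qwfr <- function(p, params) {
  th <- as_wfr_params(params)
  if (length(p) == 0L || anyNA(p) || any(p <= 0) || any(p >= 1))
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  z <- -log1p(-p)                       # -log(1 - p) > 0
  w <- -(log(z) - log(th["a"])) / th["b"]  # log of (z/a)^{-1/b}
  lsum <- ifelse(w > 35, w, log1p(exp(w)))  # log(1 + (z/a)^{-1/b})
  unname(th["alpha"] * lsum^(-1 / th["beta"]))
}

#' @rdname wfr-distribution
#' @export
rwfr <- function(n, params) {
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  qwfr(stats::runif(n), params)
}

#' @rdname wfr-distribution
#' @export
wfr_reliability <- function(t, params) {
  pwfr(t, params, lower.tail = FALSE)
}

#' @rdname wfr-distribution
#' @export
wfr_hazard <- function(t, params) {
  th <- as_wfr_params(params)
  check_positive_times(t, "t")
  xx <- (th["alpha"] / t)^th["beta"]
  unname(exp(wfr_log_hazard_core(t, xx, th)))
}

#' Gradients of reliability and hazard in the parameters
#'
#' Analytic gradients of \eqn{r(t)} and \eqn{h(t)} with respect to
#' \eqn{(a, b, \alpha, \beta)}, used by the delta method.
#'
#' @param params A [wfr_params] object.
#' @param t Positive scalar time.
#' @return A 4 x 2 matrix; rows `a`, `b`, `alpha`, `beta`; columns `r`, `h`.
#' @export
wfr_rh_grad <- function(params, t) {
  th <- as_wfr_params(params)
  check_positive_times(t, "t")
  a <- th["a"]; b <- th["b"]; alpha <- th["alpha"]; beta <- th["beta"]
  x <- (alpha / t)^beta
  lg <- log_expm1(x)                    # log(e^x - 1)
  G <- exp(-b * lg)                     # (e^x - 1)^{-b}
  r <- exp(-a * G)
  h <- exp(wfr_log_hazard_core(t, x, th))
  dGdx_factor <- exp(x - (b + 1) * lg)  # e^x (e^x - 1)^{-b-1}
  dx_dalpha <- beta * x / alpha
  dx_dbeta <- x * log(alpha / t)
  dr <- c(-G * r,
          a * lg * G * r,
          a * b * r * dGdx_factor * dx_dalpha,
          a * b * r * dGdx_factor * dx_dbeta)
  dlnh_dx <- -b - (b + 1) * exp(-lg)    # -b - (b+1)/(e^x - 1)
  dh <- c(h / a,
          h * (1 / b - x - log1p(-exp(-x))),
          h * (beta / alpha + dlnh_dx * dx_dalpha),
          h * (1 / beta + log(alpha / t) + dlnh_dx * dx_dbeta))
  out <- cbind(r = dr, h = dh)
  rownames(out) <- c("a", "b", "alpha", "beta")
  out
}
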