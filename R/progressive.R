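# Progressive type-II censoring: removal schemes, censored-sample container,
# and sample generation.

#' Progressive type-II removal scheme
#'
#' A removal plan for a life test with `n` units and `m` observed failures:
#' at the i-th failure, `removals[i]` of the surviving units are withdrawn.
#' The removals must account for all unobserved units,
#' `sum(removals) == n - m`.
#'
#' @param n Total number of units on test.
#' @param m Number of observed failures (`1 <= m <= n`).
#' @param removals Integer vector of length `m` of withdrawals, each `>= 0`.
#' @return An object of class `wfr_scheme`: a list with fields `n`, `m`,
#'   `removals`.
#' @examples
#' progressive_scheme(30, 15, c(7, 1, 2, 4, 1, rep(0, 10)))
#' @export
progressive_scheme <- function(n, m, removals) {
  n <- as.integer(n); m <- as.integer(m)
  removals <- as.integer(removals)
  if (is.na(n) || is.na(m) || n < 1 || m < 1 || m > n)
    stop("need 1 <= m <= n", call. = FALSE)
  if (length(removals) != m)
    stop(sprintf("'removals' must have length m = %d, got %d", m, length(removals)),
         call. = FALSE)
  if (anyNA(removals) || any(removals < 0))
    stop("'removals' must be nonnegative integers", call. = FALSE)
  if (sum(removals) != n - m)
    stop(sprintf("removals must sum to n - m = %d, got %d", n - m, sum(removals)),
         call. = FALSE)
  structure(list(n = n, m = m, removals = removals), class = "wfr_scheme")
}

#' @export
print.wfr_scheme <- function(x, ...) {
  cat(sprintf("Progressive type-II scheme: n = %d, m = %d\nremovals: %s\n",
              x$n, x$m, paste(x$removals, collapse = " ")))
  invisible(x)
}

#' One-point censoring schemes I, II and III
#'
#' The three standard one-point schemes place the whole removal mass
#' `n - m` at a single failure: scheme I at the first failure, scheme II at
#' the middle one (`(m + 1) / 2` for odd `m`, `m / 2` for even `m`), and
#' scheme III at the last.
#'
#' @param kind `"I"`, `"II"` or `"III"` (also accepts `"CS-I"` etc.).
#' @param n,m Total units and observed failures.
#' @return A [progressive_scheme].
#' @examples
#' cs_scheme("I", 30, 15)$removals
#' cs_scheme("II", 30, 16)$removals
#' @export
cs_scheme <- function(kind = c("I", "II", "III"), n, m) {
  kind <- sub("^CS-?", "", toupper(kind[1]))
  kind <- match.arg(kind, c("I", "II", "III"))
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || is.na(m) || m < 1 || m > n)
    stop("need 1 <= m <= n", call. = FALSE)
  pos <- switch(kind,
                I = 1L,
                II = if (m %% 2L == 1L) (m + 1L) %/% 2L else m %/% 2L,
                III = m)
  removals <- integer(m)
  removals[pos] <- n - m
  progressive_scheme(n, m, removals)
}

#' Binomial-removal scheme
#'
#' Draws a random removal scheme in which the number withdrawn at the i-th
#' failure is binomial over the units still eligible for removal:
#' \eqn{R_i \sim \mathrm{Bin}(n - m - \sum_{j<i} R_j,\; p)} for
#' \eqn{i < m}, and \eqn{R_m} absorbs whatever remains so that the removals
#' sum to `n - m`.  Uses the current R random stream.
#'
#' @param n,m Total units and observed failures.
#' @param prob Per-unit removal probability in `[0, 1]`.
#' @return A [progressive_scheme].
#' @export
binomial_removal_scheme <- function(n, m, prob) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || is.na(m) || m < 1 || m > n)
    stop("need 1 <= m <= n", call. = FALSE)
  if (length(prob) != 1L || is.na(prob) || prob < 0 || prob > 1)
    stop("'prob' must be a probability in [0, 1]", call. = FALSE)
  removals <- integer(m)
  left <- n - m
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      removals[i] <- stats::rbinom(1L, left, prob)
      left <- left - removals[i]
    }
  }
  removals[m] <- left
  progressive_scheme(n, m, removals)
}

#' Progressively censored sample
#'
#' Binds the ordered observed failure times to the removal scheme under
#' which they arose.
#'
#' @param times Strictly increasing vector of `m` positive failure times.
#' @param scheme A [progressive_scheme] with matching `m`.
#' @return An object of class `wfr_sample`: a list with fields `times` and
#'   `scheme`.
#' @export
censored_sample <- function(times, scheme) {
  if (!inherits(scheme, "wfr_scheme"))
    stop("'scheme' must be a progressive_scheme", call. = FALSE)
  times <- as.numeric(times)
  check_positive_times(times, "times")
  if (length(times) != scheme$m)
    stop(sprintf("expected m = %d times, got %d", scheme$m, length(times)),
         call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  structure(list(times = times, scheme = scheme), class = "wfr_sample")
}

#' @export
print.wfr_sample <- function(x, ...) {
  cat(sprintf("Progressively censored sample: m = %d observed of n = %d\n",
              x$scheme$m, x$scheme$n))
  print(x$times, ...)
  invisible(x)
}

#' Simulate a progressively censored Weibull-Frechet sample
#'
#' Generates the joint progressively type-II censored order statistics by
#' the Balakrishnan-Sandhu transformation: with
#' \eqn{W_i \sim U(0,1)}, set
#' \eqn{V_i = W_i^{1/(i + R_m + \dots + R_{m-i+1})}} and
#' \eqn{U_{i:m:n} = 1 - \prod_{j=m-i+1}^{m} V_j}; the failure times are the
#' WFr quantiles of the \eqn{U_{i:m:n}}.  Uses the current R random stream.
#'
#' @param params A [wfr_params] object.
#' @param scheme A [progressive_scheme].
#' @return A [censored_sample].
#' @export
rwfr_progressive <- function(params, scheme) {
  th <- as_wfr_params(params)
  if (!inherits(scheme, "wfr_scheme"))
    stop("'scheme' must be a progressive_scheme", call. = FALSE)
  u <- rprogressive_uniform(scheme)
  censored_sample(qwfr(u, th), scheme)
}

# uniform-scale progressive order statistics U_{1:m:n} < ... < U_{m:m:n}
rprogressive_uniform <- function(scheme) {
  m <- scheme$m
  R <- scheme$removals
  w <- stats::runif(m)
  # exponent for V_i: i plus removals at the last i failures
  expo <- seq_len(m) + rev(cumsum(rev(R)))[m - seq_len(m) + 1L]
  # equivalently: expo[i] = i + sum(R[(m - i + 1):m])
  v <- w^(1 / expo)
  # cumprod over (V_m, V_{m-1}, ...): element i is prod_{j=m-i+1}^{m} V_j
  u <- 1 - cumprod(rev(v))
  if (any(u <= 0) || any(u >= 1) || any(diff(u) <= 0))
    stop("degenerate uniform progressive sample (numerically tied values)",
         call. = FALSE)
  u
}

#' Apply progressive censoring to a complete sample
#'
#' Mimics the physical removal mechanism on observed data: repeatedly record
#' the smallest remaining value as the next failure, then withdraw
#' `removals[i]` of the surviving units uniformly at random without
#' replacement.  Ties are broken by the stable ordering of the input
#' positions.  Uses the current R random stream.
#'
#' @param x Complete vector of `n` positive lifetimes (any order).
#' @param scheme A [progressive_scheme] with `n == length(x)`.
#' @return A [censored_sample] of the `m` observed failures.
#' @export
apply_progressive_censoring <- function(x, scheme) {
  if (!inherits(scheme, "wfr_scheme"))
    stop("'scheme' must be a progressive_scheme", call. = FALSE)
  x <- as.numeric(x)
  check_positive_times(x, "x")
  if (length(x) != scheme$n)
    stop(sprintf("length(x) = %d but scheme has n = %d", length(x), scheme$n),
         call. = FALSE)
  pool <- order(x)                      # stable: earlier index wins ties
  observed <- numeric(scheme$m)
  for (i in seq_len(scheme$m)) {
    observed[i] <- x[pool[1L]]
    pool <- pool[-1L]
    r <- scheme$removals[i]
    if (r > 0L) pool <- pool[-sample.int(length(pool), r)]
  }
  # strict ordering for the container; perturbing ties is not meaningful here,
  # so refuse replicated observed values outright
  if (any(diff(observed) <= 0))
    stop("observed failures contain ties; progressive sample requires strictly increasing times",
         call. = FALSE)
  censored_sample(observed, scheme)
}
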