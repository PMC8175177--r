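# Monte-Carlo study harness, mean squared error, and Kolmogorov-Smirnov
# goodness of fit with the exact one-sample null distribution.

#' Mean squared error against a known truth
#'
#' \eqn{(1/M)\sum_i (\hat\psi_i - \psi)^2}.
#'
#' @param estimates Nonempty numeric vector of estimates.
#' @param truth Scalar true value.
#' @return Nonnegative scalar.
#' @export
wfr_mse <- function(estimates, truth) {
  estimates <- as.numeric(estimates)
  if (length(estimates) == 0L || anyNA(estimates))
    stop("'estimates' must be nonempty and free of NA", call. = FALSE)
  mean((estimates - truth)^2)
}

#' Seeded Monte-Carlo simulation study
#'
#' For each design (a sample size pair and one-point censoring scheme) and
#' each replicate, draws a progressively censored sample at the true
#' parameters, applies the requested estimation methods, and accumulates
#' the mean squared error of all six quantities
#' \eqn{(a, b, \alpha, \beta, r(t), h(t))} against their values at the
#' truth.  Fully reproducible from `seed`.
#'
#' Methods: `"mle"` fits by maximum likelihood; `"mcmc"` additionally runs
#' the posterior sampler on each replicate and records balanced-loss
#' estimates ([bayes_estimate]) over the `w` / `q` grids.  Replicates whose
#' fit fails are dropped and counted per design.
#'
#' @param truth A [wfr_params]: the generating parameter values.
#' @param designs Data frame with columns `n`, `m`, `kind` (censoring
#'   scheme `"I"`, `"II"` or `"III"`).
#' @param replicates Replicates per design.
#' @param methods Subset of `c("mle", "mcmc")`.
#' @param w_grid,q_grid Balanced-loss grids (MCMC only); `q = 0` entries are
#'   not allowed.
#' @param prior,n_total,burn_in Passed to [wfr_mcmc] (MCMC only).
#' @param t_eval Evaluation time for reliability and hazard.
#' @param seed Integer seed for the whole study.
#' @return An object of class `wfr_study`: list with `mse` (long data frame
#'   with columns `n`, `m`, `kind`, `method`, `quantity`, `mse`,
#'   `replicates`), `estimates` (list of replicate-by-quantity matrices per
#'   design and method), `failed` (per-design drop counts), `truth`,
#'   `truth_psi`, `seed`.
#' @export
wfr_study <- function(truth,
                      designs = data.frame(n = c(30, 50, 100),
                                           m = c(15, 30, 75),
                                           kind = "I"),
                      replicates = 200,
                      methods = "mle",
                      w_grid = c(0, 0.6), q_grid = c(-0.5, 0.5),
                      prior = wfr_prior(), n_total = 2000, burn_in = 500,
                      t_eval = 0.5, seed = 1L) {
  th <- as_wfr_params(truth)
  methods <- match.arg(methods, c("mle", "mcmc"), several.ok = TRUE)
  stopifnot(is.data.frame(designs), nrow(designs) >= 1,
            all(c("n", "m", "kind") %in% names(designs)), replicates >= 1)
  if ("mcmc" %in% methods && any(q_grid == 0))
    stop("'q_grid' must not contain 0", call. = FALSE)
  set.seed(seed)
  truth_psi <- psi_vector(th, t_eval)
  estimates <- list()
  failed <- integer(nrow(designs))
  rows <- list()
  for (d in seq_len(nrow(designs))) {
    n <- designs$n[d]; m <- designs$m[d]; kind <- as.character(designs$kind[d])
    scheme <- cs_scheme(kind, n, m)
    design_id <- sprintf("n%d_m%d_%s", n, m, kind)
    mle_mat <- matrix(NA_real_, replicates, 6,
                      dimnames = list(NULL, quantity_names))
    mcmc_mats <- list()
    if ("mcmc" %in% methods) {
      for (w in w_grid) {
        mcmc_mats[[sprintf("bsel_w%g", w)]] <- mle_mat
        for (q in q_grid) mcmc_mats[[sprintf("blinex_w%g_q%g", w, q)]] <- mle_mat
      }
    }
    for (r in seq_len(replicates)) {
      smp <- rwfr_progressive(th, scheme)
      fit <- tryCatch(suppressWarnings(wfr_fit(smp)), error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        failed[d] <- failed[d] + 1L
        next
      }
      mle_mat[r, ] <- psi_vector(fit$estimates, t_eval)
      if ("mcmc" %in% methods) {
        ch <- tryCatch(suppressWarnings(
          wfr_mcmc(smp, prior = prior, n_total = n_total, burn_in = burn_in,
                   t_eval = t_eval, fit = fit)), error = function(e) NULL)
        if (is.null(ch)) { failed[d] <- failed[d] + 1L; next }
        for (w in w_grid) {
          bsel <- vapply(quantity_names, function(qn)
            bayes_estimate(ch$draws[, qn], mle_mat[r, qn], "bsel", w = w),
            numeric(1))
          mcmc_mats[[sprintf("bsel_w%g", w)]][r, ] <- bsel
          for (q in q_grid) {
            bl <- vapply(quantity_names, function(qn)
              bayes_estimate(ch$draws[, qn], mle_mat[r, qn], "blinex",
                             w = w, q = q), numeric(1))
            mcmc_mats[[sprintf("blinex_w%g_q%g", w, q)]][r, ] <- bl
          }
        }
      }
    }
    keep <- stats::complete.cases(mle_mat)
    estimates[[design_id]] <- c(list(mle = mle_mat[keep, , drop = FALSE]),
                                lapply(mcmc_mats, function(mm)
                                  mm[stats::complete.cases(mm), , drop = FALSE]))
    for (meth in names(estimates[[design_id]])) {
      mm <- estimates[[design_id]][[meth]]
      if (nrow(mm) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, m = m, kind = kind, method = meth,
        quantity = quantity_names,
        mse = vapply(quantity_names, function(qn)
          wfr_mse(mm[, qn], truth_psi[qn]), numeric(1)),
        replicates = nrow(mm), row.names = NULL)
    }
  }
  structure(list(mse = do.call(rbind, rows), estimates = estimates,
                 failed = failed, truth = th, truth_psi = truth_psi,
                 t_eval = t_eval, seed = seed),
            class = "wfr_study")
}

#' @export
print.wfr_study <- function(x, ...) {
  cat(sprintf("Monte-Carlo study (seed %d)\n", x$seed))
  print(x$mse, ...)
  invisible(x)
}

#' Kolmogorov-Smirnov statistic against a fitted Weibull-Frechet law
#'
#' Two-sided sup-distance between the empirical distribution of `x` and the
#' WFr distribution function at `params`:
#' \eqn{D = \max_i \max\{i/n - F(y_{(i)}),\; F(y_{(i)}) - (i-1)/n\}}.
#'
#' @param x Positive observations (any order).
#' @param params A [wfr_params].
#' @return Scalar in `[0, 1]`.
#' @export
ks_statistic <- function(x, params) {
  th <- as_wfr_params(params)
  check_positive_times(x, "x")
  Fv <- pwfr(sort(x), th)
  n <- length(x)
  i <- seq_len(n)
  max(pmax(i / n - Fv, Fv - (i - 1) / n))
}

#' One-sample Kolmogorov-Smirnov p-value
#'
#' Null probability of a sup-distance at least `D` for a sample of size
#' `n`.  `method = "exact"` (default for `n <= 100`) evaluates the exact
#' finite-sample distribution by the Durbin matrix method;
#' `method = "asymptotic"` uses the alternating Kolmogorov series at
#' \eqn{\sqrt{n}\,D}.
#'
#' @param D Statistic in `[0, 1]`.
#' @param n Sample size.
#' @param method `"auto"`, `"exact"` or `"asymptotic"`.
#' @return p-value in `[0, 1]`.
#' @export
ks_pvalue <- function(D, n, method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  if (length(D) != 1L || is.na(D) || D < 0 || D > 1) stop("'D' must be in [0, 1]", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer", call. = FALSE)
  if (D == 0) return(1)
  if (method == "auto") method <- if (n <= 100) "exact" else "asymptotic"
  if (method == "exact") 1 - kolmogorov_cdf_exact(D, n)
  else kolmogorov_tail_asymptotic(sqrt(n) * D)
}

# P(sqrt(n) D_n > lambda) for large n: 2 sum_{j>=1} (-1)^{j-1} e^{-2 j^2 lambda^2}
kolmogorov_tail_asymptotic <- function(lambda, terms = 100L) {
  j <- seq_len(terms)
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))))
}

# Exact P(D_n < d) by the Durbin matrix method (Marsaglia-Tsang-Wang):
# D_n < d iff a certain (2k-1)x(2k-1) transition matrix power has positive
# probability mass; P = n!/n^n * (H^n)[k, k], computed with rescaling.
kolmogorov_cdf_exact <- function(d, n) {
  if (d <= 0) return(0)
  if (d >= 1) return(1)
  k <- ceiling(n * d)
  h <- k - n * d
  mdim <- 2L * k - 1L
  H <- matrix(0, mdim, mdim)
  for (i in seq_len(mdim))
    for (j in seq_len(mdim))
      if (i - j + 1L >= 0L) H[i, j] <- 1
  for (i in seq_len(mdim)) {
    H[i, 1] <- H[i, 1] - h^i
    H[mdim, i] <- H[mdim, i] - h^(mdim - i + 1L)
  }
  H[mdim, 1] <- H[mdim, 1] + if (2 * h - 1 > 0) (2 * h - 1)^mdim else 0
  for (i in seq_len(mdim))
    for (j in seq_len(mdim))
      if (i - j + 1L > 0L)
        H[i, j] <- H[i, j] / factorial(i - j + 1L)
  # H^n by repeated multiplication with overflow rescaling
  pw <- matrix_power_scaled(H, n)
  s <- pw$M[k, k]
  expo <- pw$expo
  for (i in seq_len(n)) {
    s <- s * i / n
    if (s < 1e-140) {
      s <- s * 1e140
      expo <- expo - 140L
    }
  }
  min(1, max(0, s * 10^expo))
}

matrix_power_scaled <- function(M, n) {
  expo <- 0L
  result <- diag(nrow(M))
  for (i in seq_len(n)) {
    result <- result %*% M
    if (max(abs(result)) > 1e140) {
      result <- result * 1e-140
      expo <- expo + 140L
    }
  }
  list(M = result, expo = expo)
}
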