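test_that("censored log-likelihood matches a per-term oracle", {
  smp <- sec_sample()
  R <- smp$scheme$removals
  set.seed(13)
  for (i in 1:5) {
    p <- random_params()
    oracle <- sum(dwfr(smp$times, p, log = TRUE) +
                    R * pwfr(smp$times, p, lower.tail = FALSE, log.p = TRUE))
    expect_lt(abs(wfr_loglik(p, smp) - oracle), 1e-8)
  }
  # complete-data reduction: all removals zero
  full <- gastric_sample()
  p <- params_a()
  expect_equal(wfr_loglik(p, full), sum(dwfr(full$times, p, log = TRUE)),
               tolerance = 1e-10)
  # finite at the published point estimates
  expect_true(is.finite(wfr_loglik(mle_row_params(), smp)))
})

test_that("analytic score equals the numeric gradient of the log-likelihood", {
  smp <- sec_sample()
  set.seed(20)
  for (i in 1:20) {
    th <- as.numeric(random_params())
    an <- wfr_score(wfr_params(th[1], th[2], th[3], th[4]), smp)
    num <- vapply(1:4, function(j) {
      h <- 1e-6 * max(1, abs(th[j]))
      tp <- th; tm <- th
      tp[j] <- th[j] + h; tm[j] <- th[j] - h
      (wfr_loglik(wfr_params(tp[1], tp[2], tp[3], tp[4]), smp) -
         wfr_loglik(wfr_params(tm[1], tm[2], tm[3], tm[4]), smp)) / (2 * h)
    }, numeric(1))
    expect_rel_equal(an, num, 1e-6)
  }
})

test_that("profile estimate of a solves its score equation", {
  # single observation at y = alpha with b = 1: denominator is e - 1
  one <- censored_sample(2, progressive_scheme(1, 1, 0L))
  expect_equal(wfr_profile_a(1, 2, 1.5, one), exp(1) - 1,
               tolerance = 1e-12)
  smp <- sec_sample()
  set.seed(31)
  for (i in 1:20) {
    q <- exp(stats::runif(3, -1, 1))
    ahat <- wfr_profile_a(q[1], q[2], q[3], smp)
    expect_gt(ahat, 0)
    s <- wfr_score(wfr_params(ahat, q[1], q[2], q[3]), smp)
    expect_lt(abs(s["a"]), 1e-8 * max(1, abs(ahat)))
  }
  # published point estimates are consistent with the profile formula
  expect_equal(wfr_profile_a(2.8097, 0.3817, 0.6267, smp), 0.1440,
               tolerance = 5e-3)
})

test_that("observed information is a symmetric numeric Hessian with inverse", {
  smp <- sec_sample()
  p <- params_a()
  I <- wfr_obs_info(p, smp)
  expect_lt(max(abs(I - t(I))), 1e-9)
  # independent oracle: second central differences of the log-likelihood
  th <- as.numeric(p)
  Hnum <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    hi <- 1e-4 * max(1, abs(th[i])); hj <- 1e-4 * max(1, abs(th[j]))
    f <- function(d1, d2) {
      tt <- th; tt[i] <- tt[i] + d1; tt[j] <- tt[j] + d2
      wfr_loglik(wfr_params(tt[1], tt[2], tt[3], tt[4]), smp)
    }
    Hnum[i, j] <- (f(hi, hj) - f(hi, -hj) - f(-hi, hj) + f(-hi, -hj)) /
      (4 * hi * hj)
  }
  expect_rel_equal(I, -Hnum, 1e-4)
  V <- solve(I)
  expect_lt(max(abs(V %*% I - diag(4))), 1e-6)
})

test_that("complete-data fit reaches a certified interior optimum", {
  fit <- wfr_fit(gastric_sample())
  expect_true(fit$converged)
  expect_lt(fit$score_norm, 1e-6)
  expect_true(all(diag(vcov(fit)) > 0))
  # the optimum dominates nearby parameter values
  th <- as.numeric(coef(fit))
  for (f in c(0.9, 1.1)) {
    pert <- wfr_params(th[1], th[2] * f, th[3] * f, th[4] / f)
    expect_gt(fit$loglik, wfr_loglik(pert, fit$sample))
  }
})

test_that("flat small-sample censored likelihood is flagged, not certified", {
  # this likelihood increases monotonically toward a degenerate boundary;
  # the fit must say so instead of reporting a spurious optimum
  fit <- suppressWarnings(wfr_fit(sec_sample()))
  expect_false(fit$converged)
  expect_error(confint(fit), "converge")
})

test_that("maximum likelihood recovers generating parameters approximately", {
  truth <- study_truth()
  sch <- cs_scheme("I", 100, 75)
  set.seed(1)
  est <- matrix(NA_real_, 50, 4)
  for (i in 1:50) {
    smp <- rwfr_progressive(truth, sch)
    ft <- tryCatch(suppressWarnings(wfr_fit(smp)), error = function(e) NULL)
    if (!is.null(ft) && ft$converged) est[i, ] <- coef(ft)
  }
  est <- est[stats::complete.cases(est), ]
  expect_gt(nrow(est), 40)
  med <- apply(est, 2, stats::median)
  expect_true(all(abs(med - as.numeric(truth)) / as.numeric(truth) < 0.25))
})

test_that("intervals at the published point estimates match the published table", {
  fe <- wfr_fit(sec_sample(), estimates = mle_row_params())
  expect_true(fe$fixed)
  ci <- wfr_asymptotic_ci(fe, level = 0.95, t_eval = 0.5)
  # delta-method reliability interval is reproduced tightly
  r_row <- ci[ci$quantity == "r", ]
  expect_equal(r_row$lower, 0.8651, tolerance = 0.005)
  expect_equal(r_row$upper, 1.0088, tolerance = 0.005)
  expect_gt(r_row$upper, 1)  # untruncated, as published
  h_row <- ci[ci$quantity == "h", ]
  expect_equal(h_row$lower, 0.0552, tolerance = 0.005)
  expect_equal(h_row$upper, 0.6241, tolerance = 0.005)
  # parameter intervals agree in shape (signed lower bounds) and roughly in value
  a_row <- ci[ci$quantity == "a", ]
  expect_lt(a_row$lower, 0)
  expect_equal(a_row$lower, -2.2774, tolerance = 0.25)
  expect_equal(a_row$upper, 2.5654, tolerance = 0.25)
  # a near-zero level collapses the interval onto the point estimate
  tiny <- confint(fe, level = 1e-9)
  expect_equal(tiny[, "lower"], tiny[, "upper"], tolerance = 1e-6)
})

test_that("delta variances are nonnegative quadratic forms", {
  fit <- wfr_fit(gastric_sample())
  for (t0 in c(0.25, 0.5, 1, 2)) {
    ci <- wfr_delta_ci(fit, t = t0)
    expect_true(all(ci[, "upper"] >= ci[, "lower"]))
  }
})
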