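test_that("gamma full conditional of a has the stated shape and rate", {
  toy <- censored_sample(c(0.5, 1.2, 2.1), progressive_scheme(6, 3, c(2, 1, 0)))
  pr <- wfr_prior(shape = c(1.5, 1, 1, 1), rate = c(2, 1, 1, 1))
  cond <- wfr_conditional_a(b = 1.3, alpha = 0.8, beta = 1.1, toy, pr)
  expect_equal(cond$shape, 3 + 1.5)
  # rate by explicit per-term summation
  y <- toy$times; R <- toy$scheme$removals
  rate_hand <- 2
  for (k in 1:3)
    rate_hand <- rate_hand + (R[k] + 1) * (exp((0.8 / y[k])^1.1) - 1)^(-1.3)
  expect_equal(cond$rate, rate_hand, tolerance = 1e-12)
  # moments of draws from the returned gamma match shape/rate
  set.seed(2)
  draws <- rgamma(2e4, cond$shape, cond$rate)
  expect_equal(mean(draws), cond$shape / cond$rate, tolerance = 0.02)
})

test_that("log conditional kernels match independent term-by-term evaluation", {
  toy <- censored_sample(c(0.6, 1.1, 1.9), progressive_scheme(5, 3, c(1, 1, 0)))
  pr <- wfr_prior(shape = c(0.5, 1.2, 0.8, 1.4), rate = c(1, 0.7, 1.1, 0.9))
  th <- wfr_params(0.4, 1.3, 0.9, 1.2)
  y <- toy$times; R <- toy$scheme$removals; m <- 3
  common <- function(a, b, alpha, beta) {
    out <- 0
    for (k in 1:3) {
      x <- (alpha / y[k])^beta
      out <- out - b * x - a * (R[k] + 1) * (exp(x) - 1)^(-b) -
        (b + 1) * log(1 - exp(-x))
    }
    out
  }
  b_val <- 1.7
  oracle_b <- (m + 1.2 - 1) * log(b_val) - 0.7 * b_val +
    common(0.4, b_val, 0.9, 1.2)
  expect_equal(wfr_log_conditional("b", b_val, th, toy, pr), oracle_b,
               tolerance = 1e-10)
  al_val <- 0.75
  oracle_al <- (m * 1.2 + 0.8 - 1) * log(al_val) - 1.1 * al_val +
    common(0.4, 1.3, al_val, 1.2)
  expect_equal(wfr_log_conditional("alpha", al_val, th, toy, pr), oracle_al,
               tolerance = 1e-10)
  be_val <- 1.45
  oracle_be <- (m + 1.4 - 1) * log(be_val) - (be_val + 1) * sum(log(y)) -
    0.9 * be_val + common(0.4, 1.3, 0.9, be_val)
  expect_equal(wfr_log_conditional("beta", be_val, th, toy, pr), oracle_be,
               tolerance = 1e-10)
  # zero mass on the negative half-line
  expect_identical(wfr_log_conditional("b", -0.5, th, toy, pr), -Inf)
})

test_that("conditional kernels are unimodal on the example data", {
  smp <- sec_sample()
  th <- wfr_params(0.2846, 2.4687, 0.5223, 0.6874)
  for (which in c("b", "alpha", "beta")) {
    center <- unclass(th)[[switch(which, b = "b", alpha = "alpha", beta = "beta")]]
    grid <- seq(0.3 * center, 3 * center, length.out = 200)
    lk <- vapply(grid, function(v) wfr_log_conditional(which, v, th, smp),
                 numeric(1))
    d <- diff(lk) > 0
    expect_equal(sum(diff(d) != 0), 1)  # rises then falls exactly once
  }
})

test_that("zero-scale proposals freeze a block and make the a-step exact", {
  smp <- sec_sample()
  init <- wfr_params(0.3, 2.5, 0.5, 0.7)
  ch <- wfr_mcmc(smp, n_total = 2500, burn_in = 0, init = init,
                 proposal_sd = c(0, 0, 0), seed = 4)
  expect_true(all(ch$draws[, "b"] == 2.5))
  expect_true(all(ch$draws[, "alpha"] == 0.5))
  expect_true(all(ch$draws[, "beta"] == 0.7))
  # with the others frozen, a is an iid draw from its gamma conditional
  cond <- wfr_conditional_a(2.5, 0.5, 0.7, smp)
  a <- ch$draws[, "a"]
  mu <- cond$shape / cond$rate
  sdv <- sqrt(cond$shape) / cond$rate
  expect_lt(abs(mean(a) - mu), 4 * sdv / sqrt(length(a)))
  expect_lt(abs(stats::sd(a) - sdv), 0.1 * sdv)
  # retained reliability/hazard are deterministic transforms of the states
  idx <- c(1, 100, 2000)
  for (i in idx) {
    st <- wfr_params(a[i], 2.5, 0.5, 0.7)
    expect_equal(unname(ch$draws[i, "r"]), wfr_reliability(0.5, st), tolerance = 1e-12)
    expect_equal(unname(ch$draws[i, "h"]), wfr_hazard(0.5, st), tolerance = 1e-12)
  }
})

test_that("posterior concentrates near the truth under informative priors", {
  truth <- c(0.5, 2.5, 0.96, 0.6)
  set.seed(2)
  smp <- rwfr_progressive(do.call(wfr_params, as.list(truth)),
                          cs_scheme("I", 100, 75))
  pr <- wfr_prior(shape = 4, rate = 4 / truth)
  ch <- suppressWarnings(
    wfr_mcmc(smp, prior = pr, n_total = 4000, burn_in = 1000,
             init = do.call(wfr_params, as.list(truth)),
             proposal_sd = 0.1 * truth[2:4], seed = 3))
  pm <- colMeans(ch$draws[, 1:4])
  psd <- apply(ch$draws[, 1:4], 2, stats::sd)
  expect_true(all(abs(pm - truth) < 2 * psd))
  expect_true(all(ch$acceptance > 0.1))
  expect_true(all(ch$draws[, "r"] > 0 & ch$draws[, "r"] < 1))
  expect_true(all(ch$draws[, 1:4] > 0))
})

test_that("credible intervals are nearest-rank order statistics", {
  expect_equal(unname(credible_interval(sample(1:100), 0.95)), c(3, 98))
  set.seed(6)
  u <- runif(1e5)
  ci <- credible_interval(u, 0.95)
  expect_equal(unname(ci), c(0.025, 0.975), tolerance = 0.005)
  x <- rnorm(501)
  ci2 <- credible_interval(x, 0.5)
  med <- stats::median(x)
  expect_lte(ci2[["lower"]], med)
  expect_gte(ci2[["upper"]], med)
  expect_error(credible_interval(numeric(0)), "nonempty")
})

test_that("balanced-loss estimates satisfy their limiting identities", {
  draws <- c(1, 2, 3)
  expect_equal(bayes_estimate(draws, mle = 7, "bsel", w = 1), 7)
  expect_equal(bayes_estimate(draws, mle = 7, "blinex", w = 1, q = 0.5), 7)
  expect_equal(bayes_estimate(draws, mle = 7, "bsel", w = 0), 2)
  for (q in c(1e-6, -1e-6)) {
    expect_equal(bayes_estimate(draws, mle = 2, "blinex", w = 0.3, q = q),
                 bayes_estimate(draws, mle = 2, "bsel", w = 0.3),
                 tolerance = 1e-5)
  }
  # log-space evaluation survives large |q * psi|
  big <- c(800, 900, 1000)
  v <- bayes_estimate(big, mle = 850, "blinex", w = 0.4, q = 1)
  expect_true(is.finite(v))
  expect_gt(v, 700)
  # BSEL is linear in w; BLINEX is monotone between its endpoints
  set.seed(10)
  d2 <- rgamma(500, 2, 1)
  ws <- seq(0, 1, by = 0.1)
  bsel <- vapply(ws, function(w) bayes_estimate(d2, 3, "bsel", w = w),
                 numeric(1))
  expect_equal(diff(bsel), rep(diff(bsel)[1], 10), tolerance = 1e-10)
  bl <- vapply(ws, function(w) bayes_estimate(d2, 3, "blinex", w = w, q = 0.5),
               numeric(1))
  expect_true(all(diff(bl) > 0) || all(diff(bl) < 0))
})

test_that("posterior summaries use sample conventions", {
  s <- posterior_summaries(c(1, 2, 3))
  expect_equal(unname(s["mean"]), 2)
  expect_equal(unname(s["median"]), 2)
  expect_equal(unname(s["variance"]), 1)  # n - 1 denominator
  expect_equal(unname(s["sd"]), 1)
  expect_equal(unname(posterior_summaries(rep(4, 10))["variance"]), 0)
  set.seed(14)
  z <- rnorm(1e5)
  expect_lt(abs(posterior_summaries(z)["skewness"]), 0.03)
  expect_error(posterior_summaries(c(1, 2)), "at least 3")
})
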