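test_that("mean squared error follows its definition", {
  expect_equal(wfr_mse(rep(2, 10), 2), 0)
  expect_equal(wfr_mse(c(1, 3), 2), 1)
  set.seed(3)
  x <- rnorm(50)
  expect_equal(wfr_mse(x, 0.3), wfr_mse(sample(x), 0.3))
  expect_error(wfr_mse(numeric(0), 1), "nonempty")
})

test_that("study harness is deterministic and consistent with stored estimates", {
  truth <- study_truth()
  designs <- data.frame(n = c(30, 50), m = c(15, 30), kind = "I")
  s1 <- suppressWarnings(wfr_study(truth, designs, replicates = 15, seed = 42))
  s2 <- suppressWarnings(wfr_study(truth, designs, replicates = 15, seed = 42))
  expect_identical(s1$mse, s2$mse)
  expect_true(all(s1$mse$mse >= 0))
  # each MSE cell equals wfr_mse applied to the stored replicate estimates
  for (id in names(s1$estimates)) {
    mm <- s1$estimates[[id]]$mle
    for (qn in colnames(mm)) {
      cell <- s1$mse$mse[s1$mse$method == "mle" & s1$mse$quantity == qn &
                           sprintf("n%d_m%d_%s", s1$mse$n, s1$mse$m, s1$mse$kind) == id]
      expect_equal(cell, wfr_mse(mm[, qn], s1$truth_psi[qn]))
    }
  }
})

test_that("study harness matches an independent two-loop reimplementation", {
  truth <- study_truth()
  designs <- data.frame(n = 30, m = 15, kind = "I")
  st <- suppressWarnings(wfr_study(truth, designs, replicates = 20, seed = 5))
  # naive loop sharing the seed and draw order
  set.seed(5)
  sch <- cs_scheme("I", 30, 15)
  est <- matrix(NA_real_, 20, 6)
  for (r in 1:20) {
    smp <- rwfr_progressive(truth, sch)
    ft <- tryCatch(suppressWarnings(wfr_fit(smp)), error = function(e) NULL)
    if (is.null(ft) || !ft$converged) next
    est[r, ] <- c(coef(ft), wfr_reliability(0.5, ft$estimates),
                  wfr_hazard(0.5, ft$estimates))
  }
  est <- est[stats::complete.cases(est), , drop = FALSE]
  naive <- colMeans((est - rep(st$truth_psi, each = nrow(est)))^2)
  got <- st$mse$mse[st$mse$method == "mle"]
  expect_equal(got, unname(naive), tolerance = 1e-12)
})

test_that("KS statistic follows the empirical sup-distance definition", {
  p <- params_a()
  # observations at the (i - 0.5)/n quantiles give exactly D = 0.5/n
  n <- 20
  x <- qwfr((seq_len(n) - 0.5) / n, p)
  expect_equal(ks_statistic(x, p), 0.5 / n, tolerance = 1e-12)
  # brute-force oracle over both one-sided gaps
  set.seed(12)
  y <- rwfr(37, p)
  Fv <- pwfr(sort(y), p)
  brute <- 0
  for (i in 1:37) {
    brute <- max(brute, abs(i / 37 - Fv[i]), abs(Fv[i] - (i - 1) / 37))
  }
  expect_equal(ks_statistic(y, p), brute, tolerance = 1e-15)
  expect_error(ks_statistic(c(-1, 2), p), "strictly positive")
})

test_that("KS p-value matches the reference distribution", {
  expect_equal(ks_pvalue(0, 30), 1)
  # exact method agrees with stats::ks.test on real data
  p <- params_a()
  set.seed(9)
  y <- rwfr(40, p)
  D <- ks_statistic(y, p)
  ref <- stats::ks.test(y, function(q) pwfr(q, p), exact = TRUE)$p.value
  expect_equal(ks_pvalue(D, 40, method = "exact"), ref, tolerance = 1e-8)
  # asymptotic method equals an independently coded alternating series
  lam <- sqrt(200) * 0.08
  j <- 1:50
  series <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lam^2))
  expect_equal(ks_pvalue(0.08, 200, method = "asymptotic"), series,
               tolerance = 1e-12)
  # large-n default switches to the asymptotic form
  expect_equal(ks_pvalue(0.08, 200), series, tolerance = 1e-12)
})

test_that("packaged datasets match their documented shape", {
  g <- gastric_cancer()
  expect_length(g, 46)
  expect_equal(min(g), 0.047)
  expect_equal(max(g), 4.033)
  expect_true(all(g > 0))
  expect_false(is.unsorted(g))
  s <- simulated_example()
  expect_s3_class(s, "wfr_sample")
  expect_equal(s$scheme$n, 30L)
  expect_equal(s$scheme$m, 15L)
  expect_equal(s$scheme$removals, c(7L, 1L, 2L, 4L, 1L, rep(0L, 10)))
  expect_equal(sum(s$scheme$removals), 15L)
  expect_equal(s$times[1], 0.2332)
  expect_equal(s$times[15], 2.987)
})

test_that("scaled study reproduces the qualitative size trend", {
  truth <- study_truth()
  designs <- data.frame(n = c(30, 100), m = c(15, 75), kind = "I")
  st <- suppressWarnings(wfr_study(truth, designs, replicates = 60, seed = 11))
  for (q in c("b", "beta")) {
    v <- st$mse$mse[st$mse$quantity == q]
    expect_lt(v[2], v[1])
  }
})
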