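# Shared fixtures, built in code.

# the 15-observation progressively censored example sample
# (n = 30, m = 15, removals 7,1,2,4,1,0,...)
sec_sample <- function() {
  censored_sample(
    c(0.2332, 0.3186, 0.7247, 0.854, 1.0203, 1.0555, 1.3103, 1.3759,
      1.4376, 1.4585, 1.61, 1.7332, 1.9045, 2.1138, 2.987),
    progressive_scheme(30, 15, c(7, 1, 2, 4, 1, rep(0, 10))))
}

# published MLE point estimates for that sample
mle_row_params <- function() wfr_params(0.1440, 2.8097, 0.3817, 0.6267)

# complete (uncensored) gastric-cancer sample as a censored_sample object
gastric_sample <- function() {
  g <- gastric_cancer()
  censored_sample(g, progressive_scheme(length(g), length(g), rep(0, length(g))))
}

# reference parameter sets used across tests
params_a <- function() wfr_params(0.5, 2.5, 0.96, 0.6)
study_truth <- function() wfr_params(0.5, 0.5, 2.0, 3.5)

# random valid parameter sets in a moderate range (seeded by caller)
random_params <- function() {
  v <- exp(stats::runif(4, -1, 1))
  wfr_params(v[1], v[2], v[3], v[4])
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(1, abs(y))), tol)
}
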