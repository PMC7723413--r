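test_that("first-passage density is a proper Wald density", {
  drift <- 0.0005; sigma <- 0.02
  # integrates to 1 and matches the closed-form mean boundary/drift
  total <- integrate(function(t) fpt_density(t, drift, sigma), 0, Inf,
                     rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
  mu <- integrate(function(t) t * fpt_density(t, drift, sigma), 0, Inf)$value
  expect_equal(mu, 1 / drift, tolerance = 1e-4)
  # CDF consistent with the density
  for (tt in c(500, 2000, 8000)) {
    expect_equal(fpt_cdf(tt, drift, sigma),
                 integrate(function(t) fpt_density(t, drift, sigma), 0, tt,
                           rel.tol = 1e-9)$value,
                 tolerance = 1e-6)
  }
  # non-positive times have zero density
  expect_equal(fpt_density(c(-1, 0), drift, sigma), c(0, 0))
  expect_error(fpt_density(1, -0.1, sigma))
})

test_that("numerically extreme regimes stay finite", {
  # tiny noise: exp(2*lambda/mu) overflows unless the CDF works in logs
  expect_false(is.nan(fpt_cdf(100, 0.001, 0.001)))
  expect_true(fpt_cdf(1e6, 0.001, 0.001) <= 1)
  expect_true(all(is.finite(fpt_density(c(1, 1e5), 1e-9, 5, log = TRUE)) |
                    fpt_density(c(1, 1e5), 1e-9, 5, log = TRUE) == -Inf))
})

test_that("sampler matches the analytic distribution", {
  set.seed(10)
  drift <- 0.0008; sigma <- 0.02
  x <- fpt_sample(5e4, drift, sigma)
  expect_equal(mean(x), 1 / drift, tolerance = 0.02)
  # KS against the analytic CDF
  ks <- suppressWarnings(
    ks.test(x, function(q) fpt_cdf(q, drift, sigma))$statistic)
  expect_lt(ks, 0.01)
})

test_that("empirical Euler-path FPT histogram matches the density", {
  # independent single-accumulator Euler oracle, written out in the test
  set.seed(11)
  drift <- 5e-4; sigma <- 0.02; dt <- 2
  n <- 2e4
  E <- numeric(n); rt <- rep(NA_real_, n); alive <- seq_len(n)
  for (step in 1:25000) {
    E[alive] <- E[alive] + drift * dt + rnorm(length(alive), 0, sigma * sqrt(dt))
    hit <- E[alive] >= 1
    rt[alive[hit]] <- step * dt
    alive <- alive[!hit]
    if (length(alive) == 0) break
  }
  rt <- rt[!is.na(rt)]
  expect_gt(length(rt), 0.999 * n)
  ks <- suppressWarnings(
    ks.test(rt, function(q) fpt_cdf(q, drift, sigma))$statistic)
  expect_lt(ks, 0.02)
})

test_that("trial likelihood is a normalised density over choice and RT", {
  p <- glam_params(1e-3, 0.3, 0.02, 1, contaminant_rate = 0)
  dl <- 0.0004; dr <- 0.0006
  total <- integrate(function(t) {
    trial_likelihood(t, "left", dl, dr, p) +
      trial_likelihood(t, "right", dl, dr, p)
  }, 0, 1e5, rel.tol = 1e-8)$value
  expect_equal(total, 1, tolerance = 1e-4)
  # contaminant mixture stays normalised
  pc <- glam_params(1e-3, 0.3, 0.02, 1, contaminant_rate = 0.05)
  total_c <- integrate(function(t) {
    trial_likelihood(t, "left", dl, dr, pc, rt_bounds = c(300, 4000)) +
      trial_likelihood(t, "right", dl, dr, pc, rt_bounds = c(300, 4000))
  }, 0, 1e5, rel.tol = 1e-8, subdivisions = 1000)$value
  expect_equal(total_c, 1, tolerance = 1e-4)
  expect_error(trial_likelihood(1000, "left", dl, dr, pc,
                                rt_bounds = c(5, 5)), "rt_bounds")
})

test_that("symmetric trials give even choice odds", {
  p <- glam_params(1e-3, 0.3, 0.02, 1, contaminant_rate = 0)
  expect_equal(choice_prob_right(5e-4, 5e-4, p), 0.5, tolerance = 1e-6)
})

test_that("analytic choice probability matches simulated races", {
  set.seed(12)
  p <- glam_params(1e-3, 0.3, 0.02, 1, contaminant_rate = 0)
  dl <- 0.00045; dr <- 0.00055
  pr <- choice_prob_right(dl, dr, p)
  sim <- simulate_choice_rt(rep(dl, 1e5), dr, p)
  expect_equal(mean(sim$choice == "right"), pr, tolerance = 0.01)
})

test_that("choice probability rises with gaze on the right when gamma < 1", {
  p <- quick_params(contaminant_rate = 0)
  d <- tiny_trials(n = 1)
  d$r_left <- 1.5; d$r_right <- 1.5
  probs <- sapply(c(0.2, 0.4, 0.6, 0.8), function(gr) {
    d$dt_left_ms <- 1000 * (1 - gr); d$dt_right_ms <- 1000 * gr
    td <- trial_drifts(d, p)
    choice_prob_right(td$drift_left, td$drift_right, p)
  })
  expect_true(all(diff(probs) > 0))
})

test_that("dataset NLL is additive, finite, and flags zero-density trials", {
  d <- tiny_trials(n = 6)
  p <- quick_params(contaminant_rate = 0)
  expect_equal(dataset_nll(d[0, ], p), 0)
  # single trial: NLL equals -log of the trial likelihood
  td <- trial_drifts(d[1, ], p)
  ll1 <- trial_likelihood(d$rt_s[1] * 1000, d$choice[1],
                          td$drift_left, td$drift_right, p, log = TRUE)
  expect_equal(dataset_nll(d[1, ], p), -ll1)
  nll <- dataset_nll(d, p)
  expect_true(is.finite(nll))
  # an impossible RT produces +Inf with a diagnostic
  d_bad <- d
  d_bad$rt_s[3] <- 1e-9
  expect_warning(out <- dataset_nll(d_bad, p), "zero-density")
  expect_equal(out, Inf, ignore_attr = TRUE)
  expect_equal(attr(out, "zero_density_trials"), 3L)
})

test_that("true parameters beat perturbed parameters in likelihood", {
  # self-consistency: on simulated data the generating parameters should
  # (almost always) dominate a doubled drift
  p <- quick_params(contaminant_rate = 0)
  p2 <- glam_params(2e-3, 0.3, 0.02, 1, contaminant_rate = 0)
  wins <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    d <- simulate_participant(p, n_trials = 500)
    if (dataset_nll(d, p) <= dataset_nll(d, p2)) wins <- wins + 1
  }
  expect_gte(wins, 19)
})
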