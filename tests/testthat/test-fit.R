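test_that("MAP recovery finds the generating parameters", {
  set.seed(30)
  true_p <- glam_params(nu = 1e-3, gamma = 0.3, sigma = 0.02, tau = 1.5)
  d <- simulate_participant(true_p, n_trials = 500)
  fit <- fit_glam(d, mode = "map")
  expect_equal(unname(fit$estimates["nu"]), true_p$nu, tolerance = 0.3)
  expect_equal(unname(fit$estimates["sigma"]), true_p$sigma, tolerance = 0.3)
  expect_equal(unname(fit$estimates["tau"]), true_p$tau, tolerance = 0.5)
  expect_lt(abs(fit$estimates["gamma"] - true_p$gamma), 0.35)
  # MAP mode is deterministic in its optimiser (draws differ by RNG only)
  fit2 <- fit_glam(d, mode = "map")
  expect_identical(fit$estimates, fit2$estimates)
})

test_that("chance-level data pull tau toward zero", {
  set.seed(31)
  true_p <- glam_params(nu = 1e-3, gamma = 0.3, sigma = 0.02, tau = 0)
  d <- simulate_participant(true_p, n_trials = 300)
  fit <- fit_glam(d, mode = "map")
  expect_lt(fit$estimates["tau"], 0.3)
})

test_that("posterior draws respect the uniform prior support", {
  set.seed(32)
  p <- quick_params()
  d <- simulate_participant(p, n_trials = 120)
  fit <- fit_glam(even_trials(d), mode = "mcmc", chains = 2,
                  tune = 150, draws = 150)
  dr <- fit$draws
  expect_true(all(dr[, "nu"] > 1e-10 & dr[, "nu"] < 0.01))
  expect_true(all(dr[, "gamma"] >= -1 & dr[, "gamma"] <= 1))
  expect_true(all(dr[, "sigma"] > 0 & dr[, "sigma"] < 5))
  expect_true(all(dr[, "tau"] >= 0 & dr[, "tau"] <= 5))
  expect_true(all(is.finite(fit$rhat)))
  expect_true(all(is.finite(fit$ess)))
  expect_equal(fit$n_divergences, 0L)
  # restricting gamma to [0, 1] is honoured
  fitr <- fit_glam(even_trials(d), mode = "map", allow_negative_gamma = FALSE)
  expect_gte(fitr$estimates["gamma"], 0)
})

test_that("NLL at fitted parameters beats the prior midpoint", {
  set.seed(33)
  p <- quick_params()
  d <- simulate_participant(p, n_trials = 200)
  fit <- fit_glam(d, mode = "map")
  mid <- glam_params(nu = 0.005, gamma = 0, sigma = 2.5, tau = 2.5)
  expect_lt(fit$nll, dataset_nll(d, mid))
})

test_that("WAIC machinery matches its definition on a toy matrix", {
  ll <- matrix(c(-1, -1.2, -0.9, -2, -2.2, -1.8), nrow = 3)
  w <- waic_from_loglik(ll)
  lppd <- sum(log(colMeans(exp(ll))))
  p_waic <- sum(apply(ll, 2, var))
  expect_equal(w$lppd, lppd)
  expect_equal(w$p_waic, p_waic)
  expect_equal(w$waic, -2 * (lppd - p_waic))
  expect_equal(sum(w$pointwise), w$waic)
})

test_that("model comparison requires identical trials and reports WAIC", {
  set.seed(34)
  p <- quick_params()
  d <- simulate_participant(p, n_trials = 120, frame = "dislike")
  f1 <- fit_glam(d, mode = "map")
  f2 <- fit_glam(d, mode = "map", transform_evidence = FALSE)
  cmp <- compare_models(f1, f2)
  expect_true(cmp$preferred %in% c("goal_relevant", "untransformed"))
  expect_equal(cmp$waic_difference,
               cmp$waic_goal_relevant - cmp$waic_untransformed)
  f3 <- fit_glam(d[1:60, ], mode = "map")
  expect_error(compare_models(f1, f3), "different trial sets")
})

test_that("even/odd split discipline is 1-based", {
  d <- tiny_trials(n = 7)
  expect_equal(odd_trials(d)$trial_index, c(1L, 3L, 5L, 7L))
  expect_equal(even_trials(d)$trial_index, c(2L, 4L, 6L))
})

test_that("RT outlier filter removes slow and extreme trials", {
  set.seed(35)
  d <- tiny_trials(n = 30)
  d$rt_s <- rlnorm(30, log(1.5), 0.15)
  d$rt_s[9] <- 12            # far beyond 3 within-participant SDs
  d$dt_left_ms <- d$rt_s * 400; d$dt_right_ms <- d$rt_s * 400
  out <- filter_rt_outliers(d)
  expect_false(9L %in% out$trial_index)
  d2 <- d[-9, ]
  d2$rt_s[5] <- 21           # above the 20 s cap
  d2$dt_left_ms <- d2$rt_s * 400; d2$dt_right_ms <- d2$rt_s * 400
  out2 <- filter_rt_outliers(d2)
  expect_false(5L %in% out2$trial_index)
  expect_gt(nrow(out), 25)
})

test_that("recovery study tabulates true vs recovered over a grid", {
  grid <- tibble::tibble(nu = 1e-3, gamma = 0.3, sigma = 0.02, tau = c(0.5, 2))
  rec <- recovery_study(grid, n_trials = 120, n_participants = 1, seed = 4)
  expect_equal(nrow(rec), 2 * 4)
  expect_true(all(c("cell", "param", "true", "recovered") %in% names(rec)))
  tau_rows <- rec[rec$param == "tau", ]
  expect_true(tau_rows$recovered[2] > tau_rows$recovered[1])
})
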