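test_that("race simulation respects symmetry and the contaminant mixture", {
  set.seed(20)
  p <- quick_params(contaminant_rate = 0)
  sim <- simulate_choice_rt(rep(5e-4, 1e5), 5e-4, p)
  expect_equal(mean(sim$choice == "right"), 0.5, tolerance = 0.005)
  expect_false(any(sim$contaminated))
  # contaminant boundary: everything is contaminated at rate 1
  pc <- glam_params(1e-3, 0.3, 0.02, 1, contaminant_rate = 0.999)
  simc <- simulate_choice_rt(rep(5e-4, 2000), 5e-4, pc, rt_bounds = c(300, 4000))
  expect_gt(mean(simc$contaminated), 0.99)
  expect_true(all(simc$rt_ms[simc$contaminated] >= 300 &
                    simc$rt_ms[simc$contaminated] <= 4000))
  expect_error(simulate_choice_rt(5e-4, 5e-4, pc), "rt_bounds")
})

test_that("mean simulated RT falls as the evidence gap grows", {
  set.seed(21)
  p <- quick_params(contaminant_rate = 0)
  mean_rt <- sapply(c(0, 0.5, 1, 2), function(gap) {
    R_l <- scaled_evidence(-gap / 2, p$tau)
    mean(simulate_choice_rt(rep(p$nu * R_l, 5000),
                            p$nu * (1 - R_l), p)$rt_ms)
  })
  expect_true(all(diff(mean_rt) < 0))
})

test_that("noiseless paths reach the closed-form balance of evidence", {
  p_det <- glam_params(nu = 1e-3, gamma = 0.3, sigma = 1e-6, tau = 1,
                       contaminant_rate = 0)
  d1 <- 1e-3; d2 <- 6e-4
  pa <- simulate_paths(d2, d1, p_det, sim_config(dt_ms = 1))
  expect_equal(pa$choice, "right")
  expect_equal(pa$rt_ms, 1 / d1, tolerance = 0.01)
  # winner at boundary 1, loser at d2/d1: delta_e = 1 - d2/d1
  expect_equal(pa$delta_e, 1 - d2 / d1, tolerance = 0.01)
  # equal drifts: both cross together, delta_e ~ 0
  pa2 <- simulate_paths(d1, d1, p_det, sim_config(dt_ms = 1))
  expect_lt(pa2$delta_e, 1e-3)
})

test_that("path and race simulators agree in distribution", {
  set.seed(22)
  p <- quick_params(contaminant_rate = 0)
  dl <- 0.00045; dr <- 0.00055
  pa <- simulate_paths(rep(dl, 2e4), dr, p, sim_config(dt_ms = 2))
  race <- simulate_choice_rt(rep(dl, 2e4), dr, p)
  expect_equal(mean(pa$choice == "right"), mean(race$choice == "right"),
               tolerance = 0.015)
  ks <- suppressWarnings(ks.test(pa$rt_ms, race$rt_ms)$statistic)
  expect_lt(ks, 0.02)
})

test_that("runaway paths are flagged after one resample", {
  p_slow <- glam_params(nu = 1e-8, gamma = 0, sigma = 1e-6, tau = 0,
                        contaminant_rate = 0)
  expect_error(
    simulate_paths(1e-8, 1e-8, p_slow, sim_config(dt_ms = 10, max_ms = 500)),
    "failed to cross")
})

test_that("out-of-sample prediction aggregates per trial and is seed-stable", {
  set.seed(23)
  p <- quick_params()
  d <- simulate_participant(p, n_trials = 30)
  odd <- odd_trials(d)
  cfg <- sim_config(n_reps_behaviour = 20)
  set.seed(5); pred1 <- out_of_sample_predict(odd, p, cfg)
  set.seed(5); pred2 <- out_of_sample_predict(odd, p, cfg)
  expect_identical(pred1, pred2)
  expect_equal(nrow(pred1), nrow(odd))
  expect_true(all(pred1$pred_p_right >= 0 & pred1$pred_p_right <= 1))
  # prediction favours the goal-relevant item more in easier trials
  set.seed(24)
  d2 <- simulate_participant(p, n_trials = 200)
  pred <- out_of_sample_predict(odd_trials(d2), p, sim_config(50))
  gap <- abs(pred$r_right - pred$r_left)
  p_goal <- ifelse(pred$r_right > pred$r_left, pred$pred_p_right,
                   1 - pred$pred_p_right)
  hi <- gap > median(gap)
  expect_gt(mean(p_goal[hi]), mean(p_goal[!hi]))
})

test_that("delta-e tables carry raw-evidence covariates and honour no-gaze-bias", {
  set.seed(25)
  p <- quick_params()
  d <- simulate_participant(p, n_trials = 40, frame = "dislike")
  odd <- odd_trials(d)
  de <- delta_e_table(odd, p, sim_config(n_reps_delta_e = 5))
  expect_equal(nrow(de), nrow(odd) * 5)
  expect_true(all(de$delta_e[!de$contaminated] >= 0))
  expect_true(all(is.na(de$delta_e[de$contaminated])))
  # covariates computed from RAW values even in the dislike frame
  expect_equal(unique(de$sum_evidence),
               unique(odd$r_left + odd$r_right))
  # forcing equal gaze removes the dwell-time dependence of the drifts
  td <- trial_drifts(odd, p, force_equal_gaze = TRUE)
  expect_equal(td$g_left, rep(0.5, nrow(odd)))
})

test_that("seeded path runs are bit-reproducible", {
  p <- quick_params(contaminant_rate = 0)
  set.seed(77); a <- simulate_paths(rep(4e-4, 50), 6e-4, p)
  set.seed(77); b <- simulate_paths(rep(4e-4, 50), 6e-4, p)
  expect_identical(a, b)
})
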