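make_group <- function(n_part = 6, n_trials = 80, frame = "like",
                       params = quick_params(), seed = 1) {
  dplyr::bind_rows(lapply(seq_len(n_part), function(i) {
    set.seed(seed + i)
    simulate_participant(params, n_trials, frame = frame,
                         participant_id = sprintf("p%02d", i))
  }))
}

test_that("choice regression finds a dominant dwell-time effect when constructed", {
  # choices determined by the dwell-time sign alone
  set.seed(50)
  d <- make_group(5, 60)
  d$choice <- ifelse(d$dt_right_ms > d$dt_left_ms, "right", "left")
  d$confidence <- sample(1:10, nrow(d), replace = TRUE)
  res <- choice_regression(d)
  g <- res$group
  est <- g$estimate[match(c("delta_dt", "delta_ev", "rt"), g$term)]
  expect_gt(est[1], abs(est[2]))
  expect_gt(est[1], abs(est[3]))
  expect_gt(est[1], 0)
})

test_that("choice regression flips the evidence slope across frames", {
  d_like <- make_group(10, 120, "like", seed = 51)
  d_dis <- make_group(10, 120, "dislike", seed = 61)
  g_like <- choice_regression(d_like)$group
  g_dis <- choice_regression(d_dis)$group
  expect_gt(g_like$estimate[g_like$term == "delta_ev"], 0)
  expect_lt(g_like$p_value[g_like$term == "delta_ev"], 0.05)
  expect_lt(g_dis$estimate[g_dis$term == "delta_ev"], 0)
  expect_lt(g_dis$p_value[g_dis$term == "delta_ev"], 0.05)
  # dwell time predicts choice positively in BOTH frames
  expect_gt(g_like$estimate[g_like$term == "delta_dt"], 0)
  expect_gt(g_dis$estimate[g_dis$term == "delta_dt"], 0)
})

test_that("random choices yield null group-level coefficients at ~5% alpha", {
  hits <- 0; n_rep <- 30
  for (s in seq_len(n_rep)) {
    set.seed(500 + s)
    d <- make_group(5, 60, seed = 500 + s)
    d$choice <- sample(c("left", "right"), nrow(d), replace = TRUE)
    g <- choice_regression(d, predictors = c("delta_ev", "delta_dt"))$group
    ps <- g$p_value[g$term != "(Intercept)"]
    if (all(ps > 0.05, na.rm = TRUE)) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.8)   # ~0.95^2 expected under the null
})

test_that("confidence regression recovers an exact linear construction", {
  set.seed(52)
  d <- make_group(4, 80)
  b_true <- 0.7
  # confidence built as an exact linear function of z-scored |delta value|
  d <- dplyr::group_by(d, participant_id)
  d <- dplyr::mutate(d, confidence = 2 +
    b_true * as.numeric(scale(abs(r_right - r_left))))
  d <- dplyr::ungroup(d)
  res <- confidence_regression(d, predictors = "abs_delta_ev")
  expect_equal(unname(res$participants[, "abs_delta_ev"]),
               rep(b_true, 4), tolerance = 1e-6)
})

test_that("delta-e regression drops constant predictors with a warning", {
  set.seed(53)
  p <- quick_params()
  d <- simulate_participant(p, 40)
  de <- delta_e_table(odd_trials(d), p, sim_config(n_reps_delta_e = 3))
  de$sum_evidence <- 1   # degenerate covariate
  expect_warning(res <- confidence_regression(de), "constant predictor")
  expect_false("sum_evidence" %in% res$term)
})

test_that("gaze influence is positive for gaze-driven choosers and signed", {
  set.seed(54)
  d <- make_group(3, 100)
  # fully gaze-driven chooser with gaze independent of value
  g_left <- runif(nrow(d))
  d$dt_left_ms <- g_left * d$rt_s * 1000
  d$dt_right_ms <- (1 - g_left) * d$rt_s * 1000
  d$choice <- ifelse(d$dt_right_ms > d$dt_left_ms, "right", "left")
  gi <- gaze_influence(d)
  expect_true(all(gi$score > 0.2))
  # anti-gaze chooser flips the sign
  d$choice <- ifelse(d$dt_right_ms > d$dt_left_ms, "left", "right")
  expect_true(all(gaze_influence(d)$score < 0))
  # value-driven chooser scores near zero
  set.seed(55)
  d2 <- make_group(3, 200)
  dv <- d2$r_right - d2$r_left
  d2$choice <- ifelse(runif(nrow(d2)) < plogis(2 * dv), "right", "left")
  g_left <- runif(nrow(d2))
  d2$dt_left_ms <- g_left * d2$rt_s * 1000
  d2$dt_right_ms <- (1 - g_left) * d2$rt_s * 1000
  expect_lt(max(abs(gaze_influence(d2)$score)), 0.1)
})

test_that("last-fixation slopes flip between frames on generated data", {
  set.seed(56)
  p <- quick_params()
  ds <- generate_dataset(6, "value", p, seed = 56)
  lf <- last_fixation_analysis(ds$trials, ds$fixations)
  g <- lf$group
  expect_gt(g$mean_slope[g$frame == "like"], 0)
  expect_lt(g$mean_slope[g$frame == "dislike"], 0)
  # frame relabelling with negated evidence flips the slope exactly
  tr <- ds$trials[ds$trials$frame == "like", ]
  tr_neg <- tr
  tr_neg$r_left <- 3 - tr$r_left
  tr_neg$r_right <- 3 - tr$r_right
  s1 <- last_fixation_analysis(tr, ds$fixations)$participants
  s2 <- last_fixation_analysis(tr_neg, ds$fixations)$participants
  expect_equal(s2$slope, -s1$slope, tolerance = 1e-6)
})

test_that("dwell-time recomputation excludes final fixations", {
  set.seed(57)
  p <- quick_params()
  ds <- generate_dataset(2, "value", p, seed = 57)
  ddt_full <- ds$trials$dt_right_ms - ds$trials$dt_left_ms
  ddt_trim <- dwell_excluding_last(ds$trials, ds$fixations, n_exclude = 2)
  n_fix <- table(paste(ds$fixations$participant_id, ds$fixations$trial_index))
  short <- n_fix[paste(ds$trials$participant_id, ds$trials$trial_index)] <= 2
  expect_true(all(is.na(ddt_trim[short])))
  expect_false(all(is.na(ddt_trim[!short])))
  expect_false(isTRUE(all.equal(ddt_trim[!short], ddt_full[!short])))
})
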