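test_that("value design reproduces the printed pair and trial counts", {
  set.seed(40)
  d <- generate_value_design()
  expect_equal(length(unique(d$pair_id)), 60)
  expect_equal(nrow(d), 240)
  expect_equal(sum(d$frame == "like"), 120)
  expect_equal(sum(d$frame == "dislike"), 120)
  expect_equal(max(d$block), 6)
  expect_equal(as.integer(table(d$block)), rep(40L, 6))
  # frames alternate by block
  frame_by_block <- tapply(d$frame, d$block, function(x) unique(x))
  expect_true(all(lengths(frame_by_block) == 1))
  expect_true(all(frame_by_block[seq(1, 5, 2)] != frame_by_block[seq(2, 6, 2)]))
  # pair-type counts
  pt <- unique(d[, c("pair_id", "pair_type")])
  expect_equal(as.integer(table(pt$pair_type)[c("high", "low", "mixed")]),
               c(15L, 15L, 30L))
})

test_that("median split and counterbalancing hold by construction", {
  set.seed(41)
  d <- generate_value_design()
  hh <- d[d$pair_type == "high", ]
  ll <- d[d$pair_type == "low", ]
  # median split: every high-pair bid is at least every low-pair bid
  expect_true(min(hh$r_left, hh$r_right) >= max(ll$r_left, ll$r_right))
  # each pair appears once per side arrangement per frame
  for (fr in c("like", "dislike")) {
    df <- d[d$frame == fr, ]
    key <- paste(df$pair_id, pmin(df$r_left, df$r_right),
                 pmax(df$r_left, df$r_right))
    expect_true(all(table(df$pair_id) == 2))
  }
  # block boundary rule
  for (b in 1:5) {
    expect_false(d$pair_id[b * 40] == d$pair_id[b * 40 + 1])
  }
  expect_error(generate_value_design(n_items = 7), "even")
})

test_that("perceptual design matches the numerosity and distractor rules", {
  set.seed(42)
  d <- generate_perceptual_design()
  expect_equal(nrow(d), 240)
  expect_equal(sum(d$frame == "most"), 120)
  expect_equal(length(unique(d$pair_id)), 30)
  # distractors are 80% of the level's target dots
  dd <- unique(d[, c("numerosity", "distractors")])
  expect_equal(dd$distractors[order(dd$numerosity)], c(40, 64, 88))
  # ten difference levels
  expect_equal(sort(unique(d$difference_pct)), seq(2, 20, 2))
  # the circles differ by d% of the numerosity (within rounding)
  gap <- abs(d$r_left - d$r_right)
  expect_equal(gap[d$numerosity == 110 & d$difference_pct == 20][1], 22)
  expect_true(all(abs(gap - d$numerosity * d$difference_pct / 100) <= 1))
  # counts stay within the fewest-transform scale
  expect_true(all(d$r_left >= 40 & d$r_left <= 133))
})

test_that("gaze generator hits its dwell-share target", {
  set.seed(43)
  gz <- generate_gaze(2400, g_left = 0.65)
  expect_equal(gz$dt_left_ms / (gz$dt_left_ms + gz$dt_right_ms), 0.65,
               tolerance = 1e-6)
  expect_equal(gz$dt_left_ms + gz$dt_right_ms, 2400, tolerance = 1e-6)
  fx <- gz$fixations
  expect_true(all(diff(fx$onset_ms) > 0))
  expect_equal(gz$gsf, nrow(fx) - 1L)
  # sides strictly alternate after merging
  if (nrow(fx) > 1) expect_true(all(fx$side[-1] != fx$side[-nrow(fx)]))
})

test_that("unbiased window and goal bias shape the gaze stream", {
  set.seed(44)
  cfg <- gaze_config(goal_dwell_share = 0.5)
  shares <- replicate(300, {
    gz <- generate_gaze(3000, g_left = rbeta(1, 6, 6), cfg)
    gz$dt_left_ms / 3000
  })
  expect_equal(mean(shares), 0.5, tolerance = 0.03)
  # early bins split evenly even when the trial share is biased
  set.seed(45)
  early <- replicate(400, {
    gz <- generate_gaze(3000, g_left = 0.7)
    fx <- gz$fixations
    idx <- findInterval(300, fx$onset_ms)
    fx$side[idx] == "left"
  })
  expect_equal(mean(early), 0.5, tolerance = 0.08)
})

test_that("generated behaviour carries the expected structure", {
  set.seed(46)
  p <- quick_params()
  skel <- generate_value_design("p01")[1:60, ]
  beh <- generate_behaviour(skel, p)
  tr <- beh$trials
  expect_equal(nrow(tr), 60)
  expect_true(all(tr$dt_left_ms + tr$dt_right_ms <= tr$rt_s * 1000 + 1e-6))
  expect_true(all(tr$confidence >= 1 & tr$confidence <= 10))
  expect_true(all(tr$confidence == round(tr$confidence)))
  # confidence correlates with the balance of evidence by construction
  ok <- !tr$contaminated
  expect_gt(cor(tr$confidence[ok], tr$delta_e[ok]), 0.5)
  expect_true(all(beh$fixations$duration_ms > 0))
})

test_that("extreme parameters drive accuracy toward certainty", {
  set.seed(47)
  p_sharp <- glam_params(nu = 2e-3, gamma = 1, sigma = 1e-4, tau = 5,
                         contaminant_rate = 0)
  d <- simulate_participant(p_sharp, n_trials = 100, frame = "like")
  d <- d[d$r_left != d$r_right, ]
  goal_right <- d$r_right > d$r_left
  acc <- mean(ifelse(d$choice == "right", goal_right, !goal_right))
  expect_gt(acc, 0.97)
})

test_that("dataset generation is reproducible and participant streams independent", {
  p <- quick_params()
  a <- generate_dataset(2, "value", p, seed = 7)
  b <- generate_dataset(2, "value", p, seed = 7)
  expect_identical(a, b)
  # adding a participant never perturbs earlier ones
  c3 <- generate_dataset(3, "value", p, seed = 7)
  expect_identical(a$trials,
                   c3$trials[c3$trials$participant_id %in% c("p01", "p02"), ])
})

test_that("like-frame choices follow value and dislike-frame choices oppose it", {
  set.seed(48)
  p <- quick_params()
  ds <- generate_dataset(4, "value", p, seed = 48)
  tr <- ds$trials
  slope <- function(d) {
    coef(glm((choice == "right") ~ I(r_right - r_left), binomial, data = d))[2]
  }
  expect_gt(slope(tr[tr$frame == "like", ]), 0)
  expect_lt(slope(tr[tr$frame == "dislike", ]), 0)
})
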