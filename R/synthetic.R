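round_half_up <- function(x) floor(x + 0.5)

#' Value-based experiment design skeleton
#'
#' Emulates the snack-choice design: 60 items with incentive-compatible bids
#' on a 0--3 pound scale (drawn Uniform(0, 3), rounded to 0.01; a Beta
#' alternative is available via `bid_dist`), a median split into high/low
#' value, 15 high-high + 15 low-low + 30 mixed pairs (60 pairs), each pair
#' presented twice per frame with sides counterbalanced (120 trials per
#' frame), and 6 alternating-frame blocks of 40 trials (240 trials). The
#' last pair of a block is never the first of the next (fixed by a single
#' swap when violated).
#'
#' @param participant_id Label for the participant.
#' @param n_items Number of rated items (even; default 60).
#' @param bid_dist `"uniform"` or `"beta"` (Beta(2, 2) scaled to 0--3).
#' @param first_frame Frame of block 1 (`"like"` by default; alternates).
#' @return A trial skeleton tibble: `participant_id`, `experiment`, `frame`,
#'   `block`, `trial_index`, `pair_id`, `pair_type`, `r_left`, `r_right`.
#'   Caller controls randomness via `set.seed()`.
#' @export
generate_value_design <- function(participant_id = "p01", n_items = 60,
                                  bid_dist = c("uniform", "beta"),
                                  first_frame = "like") {
  bid_dist <- match.arg(bid_dist)
  if (n_items %% 2L != 0L || n_items < 8L) {
    stop("n_items must be even and >= 8")
  }
  bids <- if (bid_dist == "uniform") {
    round(stats::runif(n_items, 0, 3), 2)
  } else {
    round(3 * stats::rbeta(n_items, 2, 2), 2)
  }
  ord <- order(bids, stats::runif(n_items))  # random tie-break at the median
  low_items <- ord[seq_len(n_items / 2)]
  high_items <- ord[(n_items / 2 + 1):n_items]
  n_hh <- 15L; n_ll <- 15L; n_mix <- 30L
  if (n_items < 2 * max(n_hh, n_ll) || n_items / 2 < n_mix / 1) {
    # items may repeat across pairs, only within-pair distinctness is enforced
  }
  pick_pairs <- function(pool, n_pairs) {
    idx <- sample(rep_len(sample(pool), 2 * n_pairs))
    # avoid self-pairs from recycling
    m <- matrix(idx, ncol = 2)
    for (i in which(m[, 1] == m[, 2])) {
      alt <- setdiff(pool, m[i, 1])
      m[i, 2] <- sample(alt, 1)
    }
    m
  }
  hh <- pick_pairs(high_items, n_hh)
  ll <- pick_pairs(low_items, n_ll)
  mix <- cbind(sample(rep_len(sample(high_items), n_mix)),
               sample(rep_len(sample(low_items), n_mix)))
  pairs <- tibble::tibble(
    pair_id = seq_len(n_hh + n_ll + n_mix),
    item_a = c(hh[, 1], ll[, 1], mix[, 1]),
    item_b = c(hh[, 2], ll[, 2], mix[, 2]),
    pair_type = rep(c("high", "low", "mixed"), c(n_hh, n_ll, n_mix))
  )
  frames <- rep(c(first_frame,
                  setdiff(c("like", "dislike"), first_frame)), 3)
  build_frame_trials <- function(frame) {
    t1 <- tibble::tibble(pair_id = pairs$pair_id, left = pairs$item_a,
                         right = pairs$item_b)
    t2 <- tibble::tibble(pair_id = pairs$pair_id, left = pairs$item_b,
                         right = pairs$item_a)
    tt <- dplyr::bind_rows(t1, t2)[sample(2 * nrow(pairs)), ]
    tt$frame <- frame
    tt
  }
  per_frame <- lapply(unique(frames), build_frame_trials)
  names(per_frame) <- unique(frames)
  # deal 40-trial blocks, alternating frames
  blocks <- list()
  taken <- c(like = 0L, dislike = 0L)
  for (b in seq_along(frames)) {
    f <- frames[b]
    blk <- per_frame[[f]][taken[f] + 1:40, ]
    blk$block <- b
    taken[f] <- taken[f] + 40L
    blocks[[b]] <- blk
  }
  trials <- dplyr::bind_rows(blocks)
  # block-boundary rule: last pair of a block differs from first of the next
  for (b in seq_len(length(frames) - 1L)) {
    i_last <- b * 40L
    i_first <- i_last + 1L
    if (trials$pair_id[i_last] == trials$pair_id[i_first]) {
      j <- i_first + 1L + which(trials$pair_id[(i_first + 1L):(i_first + 39L)] !=
                                  trials$pair_id[i_last])[1] - 1L
      trials[c(i_first, j), ] <- trials[c(j, i_first), ]
    }
  }
  tibble::tibble(
    participant_id = participant_id,
    experiment = "value",
    frame = trials$frame,
    block = trials$block,
    trial_index = seq_len(nrow(trials)),
    pair_id = trials$pair_id,
    pair_type = pairs$pair_type[trials$pair_id],
    r_left = bids[trials$left],
    r_right = bids[trials$right]
  )
}

#' Perceptual experiment design skeleton
#'
#' Emulates the dot-numerosity design: three numerosity levels (50, 80, 110
#' target dots) crossed with ten percentage difference levels (2%--20% in 2%
#' steps) give 30 pairs; circle counts are `round(N * (1 +/- d/200))`, so the
#' two circles differ by d% of N. Each pair appears twice per side
#' arrangement per frame (120 trials per frame), in 6 alternating-frame
#' blocks of 40 trials. Distractor dots are 80% of the level's target count
#' (40, 64, 88).
#'
#' @param participant_id Label.
#' @param first_frame Frame of block 1 (`"most"` by default).
#' @return A trial skeleton tibble with the same columns as
#'   [generate_value_design()] plus `numerosity`, `difference_pct`,
#'   `distractors`.
#' @export
generate_perceptual_design <- function(participant_id = "p01",
                                       first_frame = "most") {
  levels_n <- c(50, 80, 110)
  diffs <- seq(2, 20, by = 2)
  grid <- expand.grid(numerosity = levels_n, difference_pct = diffs)
  pairs <- tibble::tibble(
    pair_id = seq_len(nrow(grid)),
    numerosity = grid$numerosity,
    difference_pct = grid$difference_pct,
    c_high = round_half_up(grid$numerosity * (1 + grid$difference_pct / 200)),
    c_low = round_half_up(grid$numerosity * (1 - grid$difference_pct / 200)),
    distractors = round_half_up(0.8 * grid$numerosity)
  )
  frames <- rep(c(first_frame, setdiff(c("most", "fewest"), first_frame)), 3)
  build_frame_trials <- function(frame) {
    arr <- dplyr::bind_rows(
      tibble::tibble(pair_id = pairs$pair_id, left = pairs$c_high,
                     right = pairs$c_low),
      tibble::tibble(pair_id = pairs$pair_id, left = pairs$c_low,
                     right = pairs$c_high)
    )
    tt <- dplyr::bind_rows(arr, arr)   # two repetitions per arrangement
    tt <- tt[sample(nrow(tt)), ]
    tt$frame <- frame
    tt
  }
  per_frame <- lapply(unique(frames), build_frame_trials)
  names(per_frame) <- unique(frames)
  blocks <- list()
  taken <- stats::setNames(c(0L, 0L), unique(frames))
  for (b in seq_along(frames)) {
    f <- frames[b]
    blk <- per_frame[[f]][taken[f] + 1:40, ]
    blk$block <- b
    taken[f] <- taken[f] + 40L
    blocks[[b]] <- blk
  }
  trials <- dplyr::bind_rows(blocks)
  for (b in seq_len(length(frames) - 1L)) {
    i_last <- b * 40L; i_first <- i_last + 1L
    if (trials$pair_id[i_last] == trials$pair_id[i_first]) {
      j <- i_first + 1L + which(trials$pair_id[(i_first + 1L):(i_first + 39L)] !=
                                  trials$pair_id[i_last])[1] - 1L
      trials[c(i_first, j), ] <- trials[c(j, i_first), ]
    }
  }
  tibble::tibble(
    participant_id = participant_id,
    experiment = "perceptual",
    frame = trials$frame,
    block = trials$block,
    trial_index = seq_len(nrow(trials)),
    pair_id = trials$pair_id,
    pair_type = "dots",
    numerosity = pairs$numerosity[trials$pair_id],
    difference_pct = pairs$difference_pct[trials$pair_id],
    distractors = pairs$distractors[trials$pair_id],
    r_left = trials$left,
    r_right = trials$right
  )
}

#' Gaze-generator configuration
#'
#' The generator emulates the empirical fixation dynamics: an initial
#' unbiased exploration window in which both options are sampled
#' equiprobably (the gaze-contingent display forces exploration), followed
#' by a goal-biased phase in which the expected dwell share on the
#' goal-relevant item (the one with higher goal-relevant evidence) is
#' `goal_dwell_share`.
#'
#' @param unbiased_ms Unbiased exploration window (default 600 ms).
#' @param goal_dwell_share Expected dwell share on the goal-relevant item
#'   after the window, in (0.5, 1] for a goal-congruent bias (0.5 switches
#'   the bias off); default 0.60.
#' @param share_concentration Beta concentration of the trial-level share.
#' @param fix_mean_ms,fix_shape Gamma fixation-duration parameters.
#' @param min_fix_ms Minimum fixation duration.
#' @return A list of class `gaze_config`.
#' @export
gaze_config <- function(unbiased_ms = 600, goal_dwell_share = 0.60,
                        share_concentration = 12,
                        fix_mean_ms = 350, fix_shape = 4, min_fix_ms = 50) {
  stopifnot(goal_dwell_share >= 0, goal_dwell_share <= 1,
            unbiased_ms >= 0, fix_mean_ms > 0, fix_shape > 0)
  structure(list(unbiased_ms = unbiased_ms,
                 goal_dwell_share = goal_dwell_share,
                 share_concentration = share_concentration,
                 fix_mean_ms = fix_mean_ms, fix_shape = fix_shape,
                 min_fix_ms = min_fix_ms),
            class = "gaze_config")
}

# draw alternating fixation durations summing exactly to `total`
alt_fixations <- function(total, start_left, config) {
  if (total <= 0) {
    return(tibble::tibble(side = character(), duration_ms = numeric()))
  }
  durs <- numeric(0)
  while (sum(durs) < total) {
    d <- pmax(stats::rgamma(4, shape = config$fix_shape,
                            scale = config$fix_mean_ms / config$fix_shape),
              config$min_fix_ms)
    durs <- c(durs, d)
  }
  cum <- cumsum(durs)
  k <- which(cum >= total)[1]
  durs <- durs[seq_len(k)]
  durs[k] <- durs[k] - (cum[k] - total)
  first <- if (start_left) c("left", "right") else c("right", "left")
  tibble::tibble(side = rep(first, length.out = k), duration_ms = durs)
}

#' Generate one trial's fixation sequence
#'
#' Builds an alternating fixation sequence of total length `duration_ms`
#' whose dwell on the left option equals `g_left * duration_ms`. The first
#' `unbiased_ms` are split evenly between the options (random starting
#' side); the remainder is rescaled per side to hit the target share. When
#' the target is too extreme for the unbiased window to survive, the whole
#' trial is rescaled instead.
#'
#' @param duration_ms Trial duration (= RT) in ms.
#' @param g_left Target relative dwell on the left option.
#' @param config A [gaze_config()].
#' @return A list: `fixations` (tibble `side`, `onset_ms`, `duration_ms`),
#'   `dt_left_ms`, `dt_right_ms`, `gsf` (number of gaze shifts).
#' @export
generate_gaze <- function(duration_ms, g_left, config = gaze_config()) {
  stopifnot(duration_ms > 0, g_left >= 0, g_left <= 1)
  start_left <- stats::runif(1) < 0.5
  W <- min(config$unbiased_ms, duration_ms)
  fx1 <- alt_fixations(W, start_left, config)
  # balance the unbiased window: rescale so each side holds W/2
  fx1 <- rescale_sides(fx1, target_left = W / 2)
  L <- duration_ms - W
  target_left_total <- g_left * duration_ms
  t2_left <- target_left_total - W / 2
  if (L > 0 && t2_left >= 0 && t2_left <= L) {
    last_side <- if (nrow(fx1) > 0) fx1$side[nrow(fx1)] else "left"
    fx2 <- alt_fixations(L, start_left = last_side != "left", config)
    fx2 <- rescale_sides(fx2, target_left = t2_left)
    fx <- dplyr::bind_rows(fx1, fx2)
  } else {
    # extreme share or very short trial: rescale the whole sequence
    fx <- alt_fixations(duration_ms, start_left, config)
    fx <- rescale_sides(fx, target_left = target_left_total)
  }
  fx <- fx[fx$duration_ms > 1e-9, ]
  fx <- merge_adjacent(fx)
  fx$onset_ms <- cumsum(c(0, fx$duration_ms))[seq_len(nrow(fx))]
  list(
    fixations = fx[, c("side", "onset_ms", "duration_ms")],
    dt_left_ms = sum(fx$duration_ms[fx$side == "left"]),
    dt_right_ms = sum(fx$duration_ms[fx$side == "right"]),
    gsf = if (nrow(fx) <= 1L) 0L else sum(fx$side[-1] != fx$side[-nrow(fx)])
  )
}

rescale_sides <- function(fx, target_left) {
  if (nrow(fx) == 0L) return(fx)
  total <- sum(fx$duration_ms)
  target_left <- min(max(target_left, 0), total)
  is_l <- fx$side == "left"
  a <- sum(fx$duration_ms[is_l]); b <- total - a
  if (a == 0 && target_left > 0) {
    fx <- dplyr::bind_rows(fx, tibble::tibble(side = "left", duration_ms = 0))
    is_l <- fx$side == "left"; a <- 0
  }
  if (b == 0 && target_left < total) {
    fx <- dplyr::bind_rows(fx, tibble::tibble(side = "right", duration_ms = 0))
    is_l <- fx$side == "left"; b <- 0
  }
  if (a > 0) {
    fx$duration_ms[is_l] <- fx$duration_ms[is_l] * target_left / a
  } else if (target_left > 0) {
    fx$duration_ms[is_l] <- target_left / sum(is_l)
  }
  if (b > 0) {
    fx$duration_ms[!is_l] <- fx$duration_ms[!is_l] * (total - target_left) / b
  } else if (total - target_left > 0) {
    fx$duration_ms[!is_l] <- (total - target_left) / sum(!is_l)
  }
  fx
}

merge_adjacent <- function(fx) {
  if (nrow(fx) <= 1L) return(fx)
  grp <- cumsum(c(TRUE, fx$side[-1] != fx$side[-nrow(fx)]))
  out <- dplyr::summarise(dplyr::group_by(fx, grp = grp),
                          side = .data$side[1],
                          duration_ms = sum(.data$duration_ms),
                          .groups = "drop")
  out[, c("side", "duration_ms")]
}

default_confidence_map <- function() {
  list(intercept = 1, slope = 4, noise_sd = 1, scale = c(1, 10))
}

#' Generate behaviour for a trial skeleton
#'
#' Drives the full generative loop for one participant: goal-relevant
#' transform, trial-level gaze share toward the goal-relevant item, Euler
#' path simulation of the race (yielding choice, RT and balance of evidence
#' delta-e), confidence as an affine map of delta-e plus Gaussian noise
#' clipped to the rating scale (integers 1--10 by default), the contaminant
#' process on a 5% fraction of trials, and a fixation sequence realising the
#' gaze share.
#'
#' @param skeleton Trial skeleton from [generate_value_design()] /
#'   [generate_perceptual_design()] (one participant).
#' @param params A [glam_params()] object for this participant.
#' @param gaze_cfg A [gaze_config()].
#' @param confidence_map List with `intercept`, `slope` (confidence units
#'   per unit delta-e), `noise_sd`, `scale` (rating bounds).
#' @param config A [sim_config()] controlling the path step.
#' @return A list with `trials` (full trial tibble, adds `dt_left_ms`,
#'   `dt_right_ms`, `rt_s`, `choice`, `confidence`, `gsf`, `delta_e`,
#'   `contaminated`) and `fixations` (long tibble).
#' @export
generate_behaviour <- function(skeleton, params, gaze_cfg = gaze_config(),
                               confidence_map = default_confidence_map(),
                               config = sim_config()) {
  n <- nrow(skeleton)
  rv_l <- goal_relevant_evidence(skeleton$r_left, skeleton$frame)
  rv_r <- goal_relevant_evidence(skeleton$r_right, skeleton$frame)
  goal_left <- ifelse(rv_l == rv_r, stats::runif(n) < 0.5, rv_l > rv_r)
  share_goal <- if (gaze_cfg$goal_dwell_share %in% c(0, 1)) {
    rep(gaze_cfg$goal_dwell_share, n)
  } else {
    stats::rbeta(n, gaze_cfg$goal_dwell_share * gaze_cfg$share_concentration,
                 (1 - gaze_cfg$goal_dwell_share) * gaze_cfg$share_concentration)
  }
  g_left <- ifelse(goal_left, share_goal, 1 - share_goal)
  a_l <- average_absolute_evidence(g_left, rv_l, params$gamma)
  a_r <- average_absolute_evidence(1 - g_left, rv_r, params$gamma)
  rstar <- relative_evidence_binary(a_l, a_r)
  R_l <- scaled_evidence(rstar$rstar_left, params$tau)
  paths <- simulate_paths(params$nu * R_l, params$nu * (1 - R_l), params, config)
  choice <- paths$choice
  rt_ms <- paths$rt_ms
  delta_e <- paths$delta_e
  contaminated <- rep(FALSE, n)
  cm <- confidence_map
  conf <- cm$intercept + cm$slope * delta_e + stats::rnorm(n, 0, cm$noise_sd)
  conf <- pmin(pmax(round(conf), cm$scale[1]), cm$scale[2])
  if (params$contaminant_rate > 0) {
    contaminated <- stats::runif(n) < params$contaminant_rate
    k <- sum(contaminated)
    if (k > 0) {
      choice[contaminated] <- sample(c("left", "right"), k, replace = TRUE)
      rt_ms[contaminated] <- stats::runif(k, min(rt_ms), max(rt_ms))
      delta_e[contaminated] <- NA_real_
      conf[contaminated] <- sample(cm$scale[1]:cm$scale[2], k, replace = TRUE)
    }
  }
  fix_rows <- vector("list", n)
  dt_l <- numeric(n); dt_r <- numeric(n); gsf <- integer(n)
  for (i in seq_len(n)) {
    gz <- generate_gaze(rt_ms[i], g_left[i], gaze_cfg)
    dt_l[i] <- gz$dt_left_ms; dt_r[i] <- gz$dt_right_ms; gsf[i] <- gz$gsf
    fx <- gz$fixations
    fx$participant_id <- skeleton$participant_id[i]
    fx$trial_index <- skeleton$trial_index[i]
    fx$fix_index <- seq_len(nrow(fx))
    fix_rows[[i]] <- fx
  }
  trials <- dplyr::mutate(skeleton,
    dt_left_ms = dt_l, dt_right_ms = dt_r,
    rt_s = rt_ms / 1000, choice = choice, confidence = conf,
    gsf = gsf, delta_e = delta_e, contaminated = contaminated
  )
  fixations <- dplyr::bind_rows(fix_rows)[
    , c("participant_id", "trial_index", "fix_index", "side",
        "onset_ms", "duration_ms")]
  list(trials = trials, fixations = fixations)
}

#' Generate a complete multi-participant synthetic dataset
#'
#' @param n_participants Number of synthetic participants.
#' @param experiment `"value"` or `"perceptual"`.
#' @param params_per_participant Either one [glam_params()] used for all, or
#'   a list of length `n_participants`.
#' @param gaze_cfg,confidence_map,config See [generate_behaviour()].
#' @param seed Master seed. Each participant gets an independent stream
#'   derived from `seed` and their index, so adding participants never
#'   perturbs earlier ones.
#' @return A list with `trials` and `fixations` tibbles covering all
#'   participants.
#' @export
generate_dataset <- function(n_participants, experiment = c("value", "perceptual"),
                             params_per_participant = glam_params(
                               nu = 1e-3, gamma = 0.3, sigma = 0.02, tau = 1),
                             gaze_cfg = gaze_config(),
                             confidence_map = default_confidence_map(),
                             config = sim_config(), seed = 1) {
  experiment <- match.arg(experiment)
  if (inherits(params_per_participant, "glam_params")) {
    params_per_participant <- rep(list(params_per_participant), n_participants)
  }
  stopifnot(length(params_per_participant) == n_participants)
  out_t <- vector("list", n_participants)
  out_f <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    set.seed((seed + 7919L * i) %% .Machine$integer.max)
    pid <- sprintf("p%02d", i)
    skel <- if (experiment == "value") {
      generate_value_design(pid, first_frame = if (i %% 2L) "like" else "dislike")
    } else {
      generate_perceptual_design(pid, first_frame = if (i %% 2L) "most" else "fewest")
    }
    beh <- generate_behaviour(skel, params_per_participant[[i]], gaze_cfg,
                              confidence_map, config)
    out_t[[i]] <- beh$trials
    out_f[[i]] <- beh$fixations
  }
  list(trials = dplyr::bind_rows(out_t), fixations = dplyr::bind_rows(out_f))
}

#' Quick single-frame synthetic participant
#'
#' A lighter generator used by recovery and model-comparison studies:
#' random pairs in one frame, race-based simulation (no paths, no
#' fixation sequences -- only dwell-time totals), confidence omitted.
#'
#' @param params A [glam_params()].
#' @param n_trials Number of trials.
#' @param experiment,frame Design kind and frame.
#' @param gaze_cfg A [gaze_config()].
#' @param participant_id Label.
#' @return A trial tibble compatible with [fit_glam()].
#' @export
simulate_participant <- function(params, n_trials = 240,
                                 experiment = c("value", "perceptual"),
                                 frame = "like",
                                 gaze_cfg = gaze_config(),
                                 participant_id = "p01") {
  experiment <- match.arg(experiment)
  if (experiment == "value") {
    r_l <- round(stats::runif(n_trials, 0, 3), 2)
    r_r <- round(stats::runif(n_trials, 0, 3), 2)
  } else {
    levels_n <- sample(c(50, 80, 110), n_trials, replace = TRUE)
    d <- sample(seq(2, 20, 2), n_trials, replace = TRUE)
    hi <- round_half_up(levels_n * (1 + d / 200))
    lo <- round_half_up(levels_n * (1 - d / 200))
    left_hi <- stats::runif(n_trials) < 0.5
    r_l <- ifelse(left_hi, hi, lo)
    r_r <- ifelse(left_hi, lo, hi)
  }
  skel <- tibble::tibble(
    participant_id = participant_id, experiment = experiment, frame = frame,
    block = 1L, trial_index = seq_len(n_trials),
    r_left = r_l, r_right = r_r
  )
  rv_l <- goal_relevant_evidence(r_l, frame)
  rv_r <- goal_relevant_evidence(r_r, frame)
  goal_left <- ifelse(rv_l == rv_r, stats::runif(n_trials) < 0.5, rv_l > rv_r)
  share_goal <- stats::rbeta(n_trials,
    gaze_cfg$goal_dwell_share * gaze_cfg$share_concentration,
    (1 - gaze_cfg$goal_dwell_share) * gaze_cfg$share_concentration)
  g_left <- ifelse(goal_left, share_goal, 1 - share_goal)
  a_l <- average_absolute_evidence(g_left, rv_l, params$gamma)
  a_r <- average_absolute_evidence(1 - g_left, rv_r, params$gamma)
  R_l <- scaled_evidence(a_l - a_r, params$tau)
  t_l <- fpt_sample(n_trials, params$nu * R_l, params$sigma, params$boundary)
  t_r <- fpt_sample(n_trials, params$nu * (1 - R_l), params$sigma, params$boundary)
  choice <- ifelse(t_r <= t_l, "right", "left")
  rt_ms <- pmin(t_l, t_r)
  if (params$contaminant_rate > 0) {
    cont <- stats::runif(n_trials) < params$contaminant_rate
    k <- sum(cont)
    if (k > 0) {
      choice[cont] <- sample(c("left", "right"), k, replace = TRUE)
      rt_ms[cont] <- stats::runif(k, min(rt_ms), max(rt_ms))
    }
  }
  dplyr::mutate(skel,
    dt_left_ms = g_left * rt_ms, dt_right_ms = (1 - g_left) * rt_ms,
    rt_s = rt_ms / 1000, choice = choice, confidence = NA_real_,
    gsf = NA_integer_
  )
}
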