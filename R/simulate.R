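#' Simulation configuration
#'
#' @param n_reps_behaviour Repetitions per trial for out-of-sample behaviour
#'   prediction (default 50, as in the prediction protocol).
#' @param n_reps_delta_e Repetitions per trial for balance-of-evidence
#'   simulation (default 10).
#' @param dt_ms Euler step of the path simulation in ms (default 10).
#' @param max_ms Runaway guard: paths that have not crossed by this time are
#'   resampled once, then raise an error (default 1e5 ms).
#' @param no_gaze_bias Force equal gaze (g = 0.5) in every simulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_reps_behaviour = 50, n_reps_delta_e = 10,
                       dt_ms = 10, max_ms = 1e5, no_gaze_bias = FALSE) {
  stopifnot(n_reps_behaviour >= 1, n_reps_delta_e >= 1, dt_ms > 0, max_ms > 0)
  structure(list(n_reps_behaviour = n_reps_behaviour,
                 n_reps_delta_e = n_reps_delta_e,
                 dt_ms = dt_ms, max_ms = max_ms,
                 no_gaze_bias = no_gaze_bias),
            class = "sim_config")
}

#' Simulate choices and RTs from the analytic race
#'
#' Samples both accumulators' Wald first-passage times and returns the
#' winner and its crossing time. With probability `contaminant_rate` a
#' simulation is replaced by a uniform random choice and an RT drawn
#' uniformly within `rt_bounds` (flagged in the output).
#'
#' @param drift_left,drift_right Drifts per ms (vectorised; one simulated
#'   race per element).
#' @param params A [glam_params()] object.
#' @param rt_bounds `(min, max)` RT bounds in ms for contaminated draws;
#'   required when `contaminant_rate > 0`.
#' @return A tibble with columns `choice`, `rt_ms`, `contaminated`.
#' @export
simulate_choice_rt <- function(drift_left, drift_right, params,
                               rt_bounds = NULL) {
  validate_glam_params(params)
  n <- max(length(drift_left), length(drift_right))
  drift_left <- rep_len(drift_left, n)
  drift_right <- rep_len(drift_right, n)
  t_l <- fpt_sample(n, drift_left, params$sigma, params$boundary)
  t_r <- fpt_sample(n, drift_right, params$sigma, params$boundary)
  choice <- ifelse(t_r <= t_l, "right", "left")
  rt <- pmin(t_l, t_r)
  contaminated <- rep(FALSE, n)
  w <- params$contaminant_rate
  if (w > 0) {
    if (is.null(rt_bounds)) stop("rt_bounds required when contaminant_rate > 0")
    contaminated <- stats::runif(n) < w
    k <- sum(contaminated)
    if (k > 0) {
      choice[contaminated] <- sample(c("left", "right"), k, replace = TRUE)
      rt[contaminated] <- stats::runif(k, rt_bounds[1], rt_bounds[2])
    }
  }
  tibble::tibble(choice = choice, rt_ms = rt, contaminated = contaminated)
}

#' Euler path simulation of the accumulator race
#'
#' Simulates both accumulators `E_i(t) = E_i(t - 1) + drift_i * dt + eps`,
#' `eps ~ N(0, sigma * sqrt(dt))`, until one crosses the boundary, and
#' records the balance of evidence `delta_e = |E_right - E_left|` at the
#' crossing. If both cross within the same step, the accumulator with the
#' larger overshoot wins (ties are measure-zero in the continuum; the
#' deterministic rule keeps runs reproducible).
#'
#' Vectorised over trials: one path per element of the drift vectors.
#'
#' @inheritParams simulate_choice_rt
#' @param config A [sim_config()]; `dt_ms` and `max_ms` are used.
#' @return A tibble with columns `choice`, `rt_ms`, `e_final_left`,
#'   `e_final_right`, `delta_e`, `contaminated` (all FALSE here; the
#'   contaminant applies to behavioural simulation, not paths).
#' @export
simulate_paths <- function(drift_left, drift_right, params,
                           config = sim_config()) {
  validate_glam_params(params)
  n <- max(length(drift_left), length(drift_right))
  dl <- rep_len(drift_left, n)
  dr <- rep_len(drift_right, n)
  res <- euler_race(dl, dr, params$sigma, params$boundary,
                    config$dt_ms, config$max_ms)
  if (any(res$runaway)) {
    idx <- which(res$runaway)
    res2 <- euler_race(dl[idx], dr[idx], params$sigma, params$boundary,
                       config$dt_ms, config$max_ms)
    if (any(res2$runaway)) {
      stop("path simulation failed to cross the boundary by ",
           config$max_ms, " ms even after resampling (",
           sum(res2$runaway), " trial(s))")
    }
    for (f in c("choice", "rt_ms", "e_left", "e_right")) {
      res[[f]][idx] <- res2[[f]]
    }
  }
  tibble::tibble(choice = res$choice, rt_ms = res$rt_ms,
                 e_final_left = res$e_left, e_final_right = res$e_right,
                 delta_e = abs(res$e_right - res$e_left),
                 contaminated = FALSE)
}

# vectorised Euler race over active trials
euler_race <- function(dl, dr, sigma, boundary, dt_ms, max_ms) {
  n <- length(dl)
  E_l <- numeric(n); E_r <- numeric(n)
  out_choice <- character(n); out_rt <- numeric(n)
  out_el <- numeric(n); out_er <- numeric(n)
  runaway <- rep(FALSE, n)
  active <- seq_len(n)
  sd_step <- sigma * sqrt(dt_ms)
  n_steps <- ceiling(max_ms / dt_ms)
  for (step in seq_len(n_steps)) {
    k <- length(active)
    E_l[active] <- E_l[active] + dl[active] * dt_ms + stats::rnorm(k, 0, sd_step)
    E_r[active] <- E_r[active] + dr[active] * dt_ms + stats::rnorm(k, 0, sd_step)
    crossed <- E_l[active] >= boundary | E_r[active] >= boundary
    if (any(crossed)) {
      idx <- active[crossed]
      over_l <- E_l[idx] - boundary
      over_r <- E_r[idx] - boundary
      right_wins <- over_r > over_l   # larger overshoot wins; only one >= 0 usually
      out_choice[idx] <- ifelse(right_wins, "right", "left")
      out_rt[idx] <- step * dt_ms
      out_el[idx] <- E_l[idx]
      out_er[idx] <- E_r[idx]
      active <- active[!crossed]
    }
    if (length(active) == 0L) break
  }
  if (length(active) > 0L) {
    runaway[active] <- TRUE
  }
  list(choice = out_choice, rt_ms = out_rt, e_left = out_el, e_right = out_er,
       runaway = runaway)
}

#' Out-of-sample behavioural prediction
#'
#' Repeats each (odd-numbered) trial `n_reps_behaviour` times through the
#' analytic race simulator, including the 5% contaminant process, and
#' aggregates to per-trial predicted choice frequencies and mean RTs.
#'
#' @param data Trial tibble, typically restricted to odd trials via
#'   [odd_trials()].
#' @param params A [glam_params()] object (per participant).
#' @param config A [sim_config()].
#' @param transform_evidence Passed to [trial_drifts()].
#' @return `data` with added columns `pred_p_right`, `pred_mean_rt_ms`,
#'   `pred_n_contaminated`.
#' @export
out_of_sample_predict <- function(data, params, config = sim_config(),
                                  transform_evidence = TRUE) {
  d <- trial_drifts(data, params, transform_evidence = transform_evidence,
                    force_equal_gaze = config$no_gaze_bias)
  reps <- config$n_reps_behaviour
  rt_bounds <- range(data$rt_s * 1000)
  if (rt_bounds[1] >= rt_bounds[2]) rt_bounds <- rt_bounds + c(-1, 1)
  n <- nrow(d)
  sim <- simulate_choice_rt(rep(d$drift_left, each = reps),
                            rep(d$drift_right, each = reps),
                            params, rt_bounds)
  trial_of <- rep(seq_len(n), each = reps)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(trial = trial_of,
                                   right = sim$choice == "right",
                                   rt = sim$rt_ms,
                                   cont = sim$contaminated),
                    .data$trial),
    pred_p_right = mean(.data$right),
    pred_mean_rt_ms = mean(.data$rt),
    pred_n_contaminated = sum(.data$cont),
    .groups = "drop"
  )
  dplyr::bind_cols(data, agg[match(seq_len(n), agg$trial), -1])
}

#' Balance-of-evidence (delta-e) simulation table
#'
#' Runs the Euler path simulation `n_reps_delta_e` times per trial and
#' returns one row per (trial x repetition) with the balance of evidence at
#' the moment of crossing, the simulated RT and choice, and the regression
#' covariates computed from the *raw* (untransformed) evidence so that frame
#' effects stay interpretable: `sum_evidence = r_left + r_right`,
#' `abs_diff_evidence = |r_left - r_right|`.
#'
#' With `config$no_gaze_bias = TRUE` both relative gaze terms are fixed at
#' 0.5 in every repetition (the no-attentional-bias counterfactual).
#' A contaminant fraction of repetitions (per `params$contaminant_rate`)
#' is replaced by uniform choice/RT draws and flagged; their `delta_e` is
#' `NA` (undefined for a non-accumulation process).
#'
#' @inheritParams out_of_sample_predict
#' @return A tibble with columns `participant_id`, `trial_index`, `frame`,
#'   `rep`, `delta_e`, `sim_rt_ms`, `sim_choice`, `sum_evidence`,
#'   `abs_diff_evidence`, `contaminated`.
#' @export
delta_e_table <- function(data, params, config = sim_config(),
                          transform_evidence = TRUE) {
  d <- trial_drifts(data, params, transform_evidence = transform_evidence,
                    force_equal_gaze = config$no_gaze_bias)
  reps <- config$n_reps_delta_e
  n <- nrow(d)
  paths <- simulate_paths(rep(d$drift_left, each = reps),
                          rep(d$drift_right, each = reps),
                          params, config)
  out <- tibble::tibble(
    participant_id = rep(d$participant_id, each = reps),
    trial_index = rep(d$trial_index, each = reps),
    frame = rep(d$frame, each = reps),
    rep = rep(seq_len(reps), times = n),
    delta_e = paths$delta_e,
    sim_rt_ms = paths$rt_ms,
    sim_choice = paths$choice,
    sum_evidence = rep(d$r_left + d$r_right, each = reps),
    abs_diff_evidence = rep(abs(d$r_left - d$r_right), each = reps),
    contaminated = FALSE
  )
  w <- params$contaminant_rate
  if (w > 0) {
    rt_bounds <- range(data$rt_s * 1000)
    if (rt_bounds[1] >= rt_bounds[2]) rt_bounds <- rt_bounds + c(-1, 1)
    cont <- stats::runif(nrow(out)) < w
    k <- sum(cont)
    if (k > 0) {
      out$contaminated[cont] <- TRUE
      out$delta_e[cont] <- NA_real_
      out$sim_rt_ms[cont] <- stats::runif(k, rt_bounds[1], rt_bounds[2])
      out$sim_choice[cont] <- sample(c("left", "right"), k, replace = TRUE)
    }
  }
  out
}

#' Odd / even trial split
#'
#' Model fitting uses only even-numbered trials and out-of-sample prediction
#' only odd-numbered trials; `trial_index` is 1-based within participant, so
#' odd includes the first trial.
#'
#' @param data Trial tibble with a `trial_index` column.
#' @return The filtered tibble.
#' @export
odd_trials <- function(data) data[data$trial_index %% 2L == 1L, ]

#' @rdname odd_trials
#' @export
even_trials <- function(data) data[data$trial_index %% 2L == 0L, ]
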