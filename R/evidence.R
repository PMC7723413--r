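#' Evidence scale of an experiment
#'
#' The value task uses incentive-compatible bids on a 0--3 pound scale; the
#' perceptual task uses target dot counts between 40 and 133 dots (the
#' extremes of the stimulus set).
#'
#' @param experiment `"value"` or `"perceptual"`.
#' @return A list with `min` and `max` evidence bounds.
#' @export
evidence_scale <- function(experiment = c("value", "perceptual")) {
  experiment <- match.arg(experiment)
  if (experiment == "value") list(min = 0, max = 3) else list(min = 40, max = 133)
}

glam_frames <- c("like", "dislike", "most", "fewest")

#' Goal-relevant evidence transform
#'
#' Re-expresses raw evidence on the scale relevant to the task goal, so that
#' the option the participant should select always carries the higher
#' transformed evidence. `like` and `most` frames leave evidence unchanged.
#' The `dislike` frame mirrors bids on the value scale
#' (`scale_max - r`, so a 3-pound item becomes 0). The `fewest` frame mirrors
#' dot counts within the stimulus range (`scale_max - r + scale_min`, so a
#' 133-dot circle becomes 40 dots). Both transforms are involutions.
#'
#' @param r Raw evidence (vectorised).
#' @param frame One of `"like"`, `"dislike"`, `"most"`, `"fewest"`
#'   (vectorised, recycled against `r`).
#' @param scale_max,scale_min Bounds of the evidence scale; defaults are
#'   taken from [evidence_scale()] for the frame's experiment.
#' @return Transformed evidence, same length as `r`.
#' @examples
#' goal_relevant_evidence(3, "dislike")   # 0
#' goal_relevant_evidence(133, "fewest")  # 40
#' @export
goal_relevant_evidence <- function(r, frame, scale_max = NULL, scale_min = NULL) {
  frame <- as.character(frame)
  if (!all(frame %in% glam_frames)) {
    stop("unknown frame(s): ", paste(setdiff(frame, glam_frames), collapse = ", "))
  }
  if (length(frame) == 1L) frame <- rep(frame, length(r))
  stopifnot(length(frame) == length(r))
  experiment <- ifelse(frame %in% c("like", "dislike"), "value", "perceptual")
  if (is.null(scale_min)) {
    scale_min <- ifelse(experiment == "value", 0, 40)
  }
  if (is.null(scale_max)) {
    scale_max <- ifelse(experiment == "value", 3, 133)
  }
  n <- length(r)
  smin <- rep_len(scale_min, n)
  smax <- rep_len(scale_max, n)
  bad <- which(r < smin | r > smax)
  if (length(bad) > 0L) {
    i1 <- bad[1L]
    stop(sprintf("evidence outside scale bounds [%g, %g]: r = %g (element %d)",
                 smin[i1], smax[i1], r[i1], i1))
  }
  scale_min <- smin
  scale_max <- smax
  out <- r
  i <- frame == "dislike"
  out[i] <- scale_max[i] - r[i]
  i <- frame == "fewest"
  out[i] <- scale_max[i] - r[i] + scale_min[i]
  out
}

#' Relative gaze from dwell times
#'
#' `g_i = DT_i / (DT_left + DT_right)` with DT the per-trial dwell time on
#' each option.
#'
#' @param dt_left,dt_right Dwell times (ms, >= 0), vectorised.
#' @return A tibble with columns `g_left`, `g_right` (summing to 1).
#' @export
relative_gaze <- function(dt_left, dt_right) {
  stopifnot(all(dt_left >= 0), all(dt_right >= 0))
  tot <- dt_left + dt_right
  if (any(tot <= 0)) {
    stop("both dwell times are zero for trial(s): ",
         paste(utils::head(which(tot <= 0), 5L), collapse = ", "),
         " (exclude these trials upstream)")
  }
  tibble::tibble(g_left = dt_left / tot, g_right = dt_right / tot)
}

#' Gaze-weighted average absolute evidence
#'
#' `A_i = g_i * r_i + (1 - g_i) * gamma * r_i`: evidence accrues at the full
#' rate while an item is fixated and at rate `gamma * r_i` while it is not.
#' Attention acts multiplicatively on evidence.
#'
#' @param g Relative gaze in `[0, 1]`.
#' @param r (Goal-relevant) evidence.
#' @param gamma Gaze-bias weight.
#' @return Average absolute evidence, same length as `r`.
#' @export
average_absolute_evidence <- function(g, r, gamma) {
  stopifnot(all(g >= 0 & g <= 1))
  g * r + (1 - g) * gamma * r
}

#' Relative evidence for a binary choice
#'
#' In the binary case each item's relative evidence is its average absolute
#' evidence minus the other item's: `rstar_left = A_left - A_right` and
#' `rstar_right = -rstar_left`.
#'
#' @param a_left,a_right Average absolute evidence per item.
#' @return A tibble with columns `rstar_left`, `rstar_right`.
#' @export
relative_evidence_binary <- function(a_left, a_right) {
  d <- a_left - a_right
  tibble::tibble(rstar_left = d, rstar_right = -d)
}

#' Logistic scaling of relative evidence
#'
#' `R_i = 1 / (1 + exp(-tau * rstar_i))`. The sensitivity `tau` controls how
#' strongly differences in relative evidence separate the two accumulation
#' rates; `tau = 0` collapses both to 0.5.
#'
#' @param rstar Relative evidence.
#' @param tau Sensitivity (>= 0).
#' @return Scaled evidence in (0, 1).
#' @export
scaled_evidence <- function(rstar, tau) {
  stopifnot(tau >= 0)
  stats::plogis(tau * rstar)
}

#' Per-trial accumulator drift rates
#'
#' Runs the full evidence pipeline for each trial of a dataset: goal-relevant
#' transform (optional), relative gaze, gaze-weighted average absolute
#' evidence, binary relative evidence, logistic scaling, and finally the
#' drift rates `nu * R_i` (per ms) for the left and right accumulators.
#'
#' @param data Trial tibble with columns `frame`, `r_left`, `r_right`,
#'   `dt_left_ms`, `dt_right_ms` (see [read_trials()] for the full schema).
#' @param params A [glam_params()] object.
#' @param transform_evidence Apply the goal-relevant transform in `dislike` /
#'   `fewest` frames (default TRUE). Setting this to FALSE fits/simulates the
#'   frame-blind model that accumulates raw evidence.
#' @param force_equal_gaze Replace observed relative gaze with 0.5/0.5
#'   (the no-gaze-bias counterfactual).
#' @return `data` with added columns `g_left`, `g_right`, `rv_left`,
#'   `rv_right` (goal-relevant evidence), `rstar_left`, `rstar_right`,
#'   `R_left`, `R_right`, `drift_left`, `drift_right`.
#' @export
trial_drifts <- function(data, params, transform_evidence = TRUE,
                         force_equal_gaze = FALSE) {
  validate_glam_params(params)
  rv_l <- if (transform_evidence) {
    goal_relevant_evidence(data$r_left, data$frame)
  } else {
    data$r_left
  }
  rv_r <- if (transform_evidence) {
    goal_relevant_evidence(data$r_right, data$frame)
  } else {
    data$r_right
  }
  g <- if (force_equal_gaze) {
    tibble::tibble(g_left = rep(0.5, nrow(data)), g_right = 0.5)
  } else {
    relative_gaze(data$dt_left_ms, data$dt_right_ms)
  }
  a_l <- average_absolute_evidence(g$g_left, rv_l, params$gamma)
  a_r <- average_absolute_evidence(g$g_right, rv_r, params$gamma)
  rs <- relative_evidence_binary(a_l, a_r)
  R_l <- scaled_evidence(rs$rstar_left, params$tau)
  R_r <- scaled_evidence(rs$rstar_right, params$tau)
  dplyr::mutate(data,
    g_left = g$g_left, g_right = g$g_right,
    rv_left = rv_l, rv_right = rv_r,
    rstar_left = rs$rstar_left, rstar_right = rs$rstar_right,
    R_left = R_l, R_right = R_r,
    drift_left = params$nu * R_l,
    drift_right = params$nu * R_r
  )
}
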