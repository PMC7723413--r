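#' Likelihood of one (choice, RT) pair under the GLAM race
#'
#' The two accumulators race to the fixed boundary; the winner determines the
#' choice and the crossing time the RT. With constant drifts each accumulator's
#' first-passage time is Wald, so the (choice, rt) density is
#' `f_chosen(rt) * (1 - F_other(rt))`, mixed with a contaminant component that
#' chooses uniformly between the two options and draws the RT uniformly within
#' the participant's observed RT range:
#' `(1 - w) f_c(rt) S_o(rt) + w * 0.5 * Unif(rt; rt_bounds)`.
#'
#' @param rt_ms Response time(s) in ms.
#' @param choice `"left"` or `"right"` (vectorised).
#' @param drift_left,drift_right Accumulator drifts (per ms), e.g. from
#'   [trial_drifts()].
#' @param params A [glam_params()] object.
#' @param rt_bounds Numeric length-2 `(min, max)` of the participant's
#'   observed RTs in ms, used by the contaminant component. Required whenever
#'   `params$contaminant_rate > 0`.
#' @param log Return log density.
#' @return Density (per ms) of the observed (choice, rt) pair(s).
#' @export
trial_likelihood <- function(rt_ms, choice, drift_left, drift_right, params,
                             rt_bounds = NULL, log = FALSE) {
  validate_glam_params(params)
  w <- params$contaminant_rate
  if (w > 0) {
    if (is.null(rt_bounds) || length(rt_bounds) != 2L ||
        rt_bounds[1] >= rt_bounds[2]) {
      stop("contaminant mixture needs rt_bounds = c(min, max) with min < max")
    }
  }
  chosen_r <- choice == "right"
  f_c <- fpt_density(rt_ms, ifelse(chosen_r, drift_right, drift_left),
                     params$sigma, params$boundary)
  S_o <- fpt_cdf(rt_ms, ifelse(chosen_r, drift_left, drift_right),
                 params$sigma, params$boundary, lower.tail = FALSE)
  dens <- (1 - w) * f_c * S_o
  if (w > 0) {
    in_b <- rt_ms >= rt_bounds[1] & rt_ms <= rt_bounds[2]
    dens <- dens + w * 0.5 * in_b / (rt_bounds[2] - rt_bounds[1])
  }
  if (log) base::log(dens) else dens
}

#' Dataset negative log-likelihood
#'
#' Sum of `-log` trial likelihoods over a (pre-processed) trial table. Trials
#' with zero density make the result `+Inf`; the offending trial indices are
#' attached as attribute `"zero_density_trials"` and reported in a warning.
#'
#' @param data Trial tibble carrying `rt_s` and `choice`; drifts are computed
#'   via [trial_drifts()] unless columns `drift_left` / `drift_right` are
#'   already present.
#' @param params A [glam_params()] object.
#' @param rt_bounds Optional `(min, max)` RT bounds in ms for the contaminant
#'   component; defaults to the range observed in `data`.
#' @param transform_evidence Passed to [trial_drifts()].
#' @return The negative log-likelihood (scalar).
#' @export
dataset_nll <- function(data, params, rt_bounds = NULL,
                        transform_evidence = TRUE) {
  if (nrow(data) == 0L) return(0)
  if (!all(c("drift_left", "drift_right") %in% names(data))) {
    data <- trial_drifts(data, params, transform_evidence = transform_evidence)
  }
  rt_ms <- data$rt_s * 1000
  if (is.null(rt_bounds) && params$contaminant_rate > 0) {
    rt_bounds <- range(rt_ms)
    if (rt_bounds[1] >= rt_bounds[2]) {
      rt_bounds <- rt_bounds + c(-1, 1)  # degenerate single-RT dataset
    }
  }
  ll <- trial_likelihood(rt_ms, data$choice, data$drift_left,
                         data$drift_right, params, rt_bounds, log = TRUE)
  if (any(!is.finite(ll))) {
    bad <- which(!is.finite(ll))
    warning("zero-density trials at indices: ",
            paste(utils::head(bad, 10L), collapse = ", "))
    out <- Inf
    attr(out, "zero_density_trials") <- bad
    return(out)
  }
  -sum(ll)
}

#' Analytic choice probability of the race
#'
#' Probability that the right accumulator wins,
#' `P(right) = integral f_right(t) S_left(t) dt`, by adaptive quadrature.
#' Without the contaminant component the two choice probabilities sum to 1.
#'
#' @param drift_left,drift_right Drifts per ms.
#' @param params A [glam_params()] object (only `sigma`, `boundary` and
#'   `contaminant_rate` are used; contaminant adds `w * 0.5` to each side).
#' @return P(choice = right), vectorised over trials.
#' @export
choice_prob_right <- function(drift_left, drift_right, params) {
  validate_glam_params(params)
  n <- max(length(drift_left), length(drift_right))
  drift_left <- rep_len(drift_left, n)
  drift_right <- rep_len(drift_right, n)
  w <- params$contaminant_rate
  vapply(seq_len(n), function(i) {
    f <- function(t) {
      fpt_density(t, drift_right[i], params$sigma, params$boundary) *
        fpt_cdf(t, drift_left[i], params$sigma, params$boundary,
                lower.tail = FALSE)
    }
    # integrate over a generous multiple of both accumulators' time scales
    upper <- 50 * params$boundary / min(drift_left[i], drift_right[i])
    p_race <- stats::integrate(f, 0, upper, rel.tol = 1e-8,
                               subdivisions = 500L)$value
    (1 - w) * p_race + w * 0.5
  }, numeric(1))
}
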