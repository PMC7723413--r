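z_score <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# L2-penalised logistic regression by IRLS; fallback for separated fits.
# X includes no intercept column; the intercept is unpenalised.
ridge_logistic <- function(X, y, lambda = 0.05, maxit = 50) {
  X1 <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    XtW <- t(X1 * w)
    beta_new <- tryCatch(
      drop(solve(XtW %*% X1 + pen, XtW %*% z)),
      error = function(e) beta
    )
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  stats::setNames(beta, colnames(X1))
}

fit_logistic_safe <- function(X, y, lambda = 0.05) {
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  co <- stats::coef(fit)
  separated <- !fit$converged || any(!is.finite(co)) || any(abs(co) > 15)
  if (separated) {
    co <- ridge_logistic(as.matrix(X), y, lambda)
    attr(co, "ridge") <- TRUE
  }
  co
}

group_level_test <- function(coef_mat) {
  terms <- colnames(coef_mat)
  dplyr::bind_rows(lapply(terms, function(tm) {
    x <- coef_mat[, tm]
    x <- x[is.finite(x)]
    if (length(x) < 2L || stats::sd(x) < 1e-10 * max(abs(x), 1)) {
      # (numerically) constant coefficients: no group-level dispersion
      return(tibble::tibble(term = tm, estimate = mean(x), se = NA_real_,
                            statistic = NA_real_, df = NA_real_,
                            p_value = NA_real_, n_participants = length(x)))
    }
    tt <- stats::t.test(x)
    tibble::tibble(term = tm, estimate = unname(tt$estimate),
                   se = stats::sd(x) / sqrt(length(x)),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   n_participants = length(x))
  }))
}

#' Two-stage choice regression
#'
#' First stage: per participant, a logistic regression of choosing the
#' right-hand option on within-participant z-scored predictors -- the
#' evidence difference `delta_ev` (right minus left raw evidence), `rt`,
#' summed evidence `sum_ev`, dwell-time difference `delta_dt` (right minus
#' left) and `conf` (when available). Second stage: a one-sample t test of
#' each coefficient across participants. Participants whose logistic fit
#' separates are re-fit with a small L2 ridge penalty and flagged.
#'
#' @param data Trial tibble (typically one frame).
#' @param predictors Character subset of
#'   `c("delta_ev", "rt", "sum_ev", "delta_dt", "conf")`.
#' @param delta_dt Optional replacement column of dwell-time differences
#'   (e.g. from [dwell_excluding_last()] for the robustness re-analysis).
#' @return A list of class `gg_regression` with `group` (coefficient table:
#'   term, estimate, se, statistic, df, p_value), `participants` (matrix of
#'   per-participant coefficients), `ridge_participants`, `label`.
#' @export
choice_regression <- function(data,
                              predictors = c("delta_ev", "rt", "sum_ev",
                                             "delta_dt", "conf"),
                              delta_dt = NULL) {
  stopifnot(length(unique(data$participant_id)) >= 2)
  d <- tibble::tibble(
    participant_id = data$participant_id,
    y = as.numeric(data$choice == "right"),
    delta_ev = data$r_right - data$r_left,
    rt = data$rt_s,
    sum_ev = data$r_left + data$r_right,
    delta_dt = if (is.null(delta_dt)) data$dt_right_ms - data$dt_left_ms
               else delta_dt,
    conf = if ("confidence" %in% names(data)) data$confidence else NA_real_
  )
  predictors <- intersect(predictors, names(d))
  if (all(is.na(d$conf))) predictors <- setdiff(predictors, "conf")
  two_stage(d, predictors, family = "binomial",
            label = paste("choice_right ~", paste(predictors, collapse = " + ")))
}

two_stage <- function(d, predictors, family, label) {
  pids <- unique(d$participant_id)
  coefs <- list(); ridge_flag <- character(0)
  for (pid in pids) {
    dd <- d[d$participant_id == pid, ]
    X <- sapply(predictors, function(p) z_score(dd[[p]]))
    keep <- apply(X, 2, function(x) stats::sd(x) > 0)
    if (!all(keep)) {
      warning("constant predictor(s) dropped for ", pid, ": ",
              paste(predictors[!keep], collapse = ", "))
    }
    X <- X[, keep, drop = FALSE]
    if (ncol(X) == 0L) next
    if (family == "binomial") {
      co <- fit_logistic_safe(X, dd$y)
      if (isTRUE(attr(co, "ridge"))) ridge_flag <- c(ridge_flag, pid)
    } else {
      co <- stats::coef(stats::lm(dd$y ~ X))
      names(co) <- c("(Intercept)", colnames(X))
    }
    coefs[[pid]] <- co
  }
  terms <- c("(Intercept)", predictors)
  mat <- t(vapply(coefs, function(co) {
    stats::setNames(co[terms], terms)
  }, numeric(length(terms))))
  colnames(mat) <- terms
  structure(list(group = group_level_test(mat), participants = mat,
                 ridge_participants = ridge_flag, label = label),
            class = "gg_regression")
}

#' @export
print.gg_regression <- function(x, ...) {
  cat("<gg_regression>", x$label, "\n")
  print(as.data.frame(x$group), digits = 3)
  if (length(x$ridge_participants) > 0) {
    cat("ridge fallback used for:", paste(x$ridge_participants, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Confidence / balance-of-evidence regression
#'
#' Two modes, selected by the input's columns:
#'
#' * A `delta_e` simulation table (from [delta_e_table()]): pooled linear
#'   regression `delta_e ~ abs_diff_evidence + sim_rt + sum_evidence` with
#'   predictors and response z-scored within participant; contaminated
#'   repetitions are excluded. Returns the pooled coefficient table (the
#'   sign of `sum_evidence` is the frame-flip quantity of interest).
#' * A trial table with a `confidence` column: two-stage linear regression
#'   of confidence on `abs_delta_ev`, `rt`, `sum_ev`, `delta_dt`, `gsf`.
#'
#' @param x Trial tibble or delta-e table.
#' @param predictors For the trial mode, subset of
#'   `c("abs_delta_ev", "rt", "sum_ev", "delta_dt", "gsf")`.
#' @return A `gg_regression` (trial mode) or tibble of pooled coefficients
#'   (delta-e mode: term, estimate, se, statistic, df, p_value).
#' @export
confidence_regression <- function(x,
                                  predictors = c("abs_delta_ev", "rt",
                                                 "sum_ev", "delta_dt", "gsf")) {
  if (all(c("delta_e", "sim_rt_ms", "abs_diff_evidence") %in% names(x))) {
    d <- x[!x$contaminated & is.finite(x$delta_e), ]
    zs <- function(v) stats::ave(v, d$participant_id, FUN = z_score)
    df <- data.frame(
      delta_e = zs(d$delta_e),
      abs_diff_evidence = zs(d$abs_diff_evidence),
      sim_rt = zs(d$sim_rt_ms),
      sum_evidence = zs(d$sum_evidence)
    )
    keep <- vapply(df[-1], function(v) stats::sd(v) > 0, logical(1))
    if (!all(keep)) {
      warning("constant predictor(s) dropped: ",
              paste(names(keep)[!keep], collapse = ", "))
      df <- df[, c(TRUE, keep)]
    }
    fit <- stats::lm(delta_e ~ ., data = df)
    sm <- summary(fit)$coefficients
    return(tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                          se = sm[, 2], statistic = sm[, 3],
                          df = fit$df.residual, p_value = sm[, 4]))
  }
  stopifnot("confidence" %in% names(x))
  d <- tibble::tibble(
    participant_id = x$participant_id,
    y = x$confidence,
    abs_delta_ev = abs(x$r_right - x$r_left),
    rt = x$rt_s,
    sum_ev = x$r_left + x$r_right,
    delta_dt = x$dt_right_ms - x$dt_left_ms,
    gsf = if ("gsf" %in% names(x)) x$gsf else NA_real_
  )
  predictors <- intersect(predictors, names(d))
  if (all(is.na(d$gsf))) predictors <- setdiff(predictors, "gsf")
  two_stage(d, predictors, family = "gaussian",
            label = paste("confidence ~", paste(predictors, collapse = " + ")))
}

#' Gaze influence on choice
#'
#' Residual choice probability after removing the evidence-based
#' prediction: per participant, a logistic regression of choosing right on
#' the evidence difference gives fitted probabilities; the residual
#' (choice minus fitted) is averaged with its sign aligned to the
#' dwell-time difference. Positive scores mean the longer-gazed option is
#' chosen above and beyond what its evidence predicts.
#'
#' @param data Trial tibble.
#' @return Tibble: `participant_id`, `score`, `n_trials`, `degenerate`
#'   (TRUE if the evidence logistic required the ridge fallback).
#' @export
gaze_influence <- function(data) {
  dplyr::bind_rows(lapply(split(data, data$participant_id), function(dd) {
    if (nrow(dd) < 30) {
      warning("fewer than 30 trials for ", dd$participant_id[1])
    }
    y <- as.numeric(dd$choice == "right")
    dv <- dd$r_right - dd$r_left
    co <- fit_logistic_safe(matrix(dv, dimnames = list(NULL, "dv")), y)
    p_hat <- stats::plogis(co[1] + co[2] * dv)
    resid <- y - p_hat
    dgaze <- dd$dt_right_ms - dd$dt_left_ms
    aligned <- ifelse(dgaze > 0, resid, ifelse(dgaze < 0, -resid, 0))
    tibble::tibble(participant_id = dd$participant_id[1],
                   score = mean(aligned), n_trials = nrow(dd),
                   degenerate = isTRUE(attr(co, "ridge")))
  }))
}

#' Last-fixation analysis
#'
#' For each trial with fixations, tests whether the last-fixated option was
#' chosen, as a logistic function of the evidence advantage of the
#' last-fixated option (its raw evidence minus the other option's,
#' z-scored within participant). Returns per-participant slopes and a
#' group-level t test, per frame.
#'
#' @param trials Trial tibble.
#' @param fixations Long fixation tibble (`participant_id`, `trial_index`,
#'   `side`, `onset_ms`, ...).
#' @return A list with `participants` (tibble: participant_id, frame,
#'   slope, intercept) and `group` (per-frame t test on the slopes).
#' @export
last_fixation_analysis <- function(trials, fixations) {
  last_fix <- dplyr::summarise(
    dplyr::group_by(fixations, .data$participant_id, .data$trial_index),
    last_side = .data$side[which.max(.data$onset_ms)], .groups = "drop")
  d <- dplyr::inner_join(trials, last_fix,
                         by = c("participant_id", "trial_index"))
  if (nrow(d) == 0L) stop("no trials with fixation data")
  per <- dplyr::bind_rows(lapply(
    split(d, list(d$participant_id, d$frame), drop = TRUE), function(dd) {
      y <- as.numeric(dd$last_side == dd$choice)
      ev_last <- ifelse(dd$last_side == "right", dd$r_right, dd$r_left)
      ev_other <- ifelse(dd$last_side == "right", dd$r_left, dd$r_right)
      x <- z_score(ev_last - ev_other)
      co <- fit_logistic_safe(matrix(x, dimnames = list(NULL, "x")), y)
      tibble::tibble(participant_id = dd$participant_id[1],
                     frame = dd$frame[1],
                     intercept = unname(co[1]), slope = unname(co[2]),
                     ridge = isTRUE(attr(co, "ridge")))
    }))
  group <- dplyr::bind_rows(lapply(split(per, per$frame), function(pp) {
    x <- pp$slope[is.finite(pp$slope)]
    tt <- stats::t.test(x)
    tibble::tibble(frame = pp$frame[1], mean_slope = mean(x),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   n_participants = length(x))
  }))
  list(participants = per, group = group)
}

#' Dwell-time difference excluding the final fixations
#'
#' Recomputes per-trial right-minus-left dwell time after dropping the last
#' `n_exclude` fixations of every trial (the robustness re-analysis that
#' checks the choice regression is not carried by the final fixation and
#' its immediate predecessor).
#'
#' @param trials Trial tibble (keyed by `participant_id`, `trial_index`).
#' @param fixations Long fixation tibble.
#' @param n_exclude Number of final fixations to drop (default 2).
#' @return Numeric vector aligned with `trials` rows (NA for trials whose
#'   fixations are all excluded).
#' @export
dwell_excluding_last <- function(trials, fixations, n_exclude = 2) {
  agg <- dplyr::summarise(
    dplyr::group_by(fixations, .data$participant_id, .data$trial_index),
    ddt = {
      o <- order(.data$onset_ms)
      keep <- o[seq_len(max(0L, length(o) - n_exclude))]
      if (length(keep) == 0L) NA_real_ else {
        sum(.data$duration_ms[keep][.data$side[keep] == "right"]) -
          sum(.data$duration_ms[keep][.data$side[keep] == "left"])
      }
    }, .groups = "drop")
  agg$ddt[match(paste(trials$participant_id, trials$trial_index),
                paste(agg$participant_id, agg$trial_index))]
}
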