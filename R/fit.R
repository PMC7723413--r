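#' @keywords internal
#' Build a fast pointwise log-likelihood closure for one participant
#'
#' Precomputes the gaze/evidence terms so that each evaluation at a new
#' theta = (nu, gamma, sigma, tau) only costs a handful of vector ops:
#' rstar = P + gamma * Q with P, Q fixed by the data.
make_loglik_fun <- function(data, transform_evidence = TRUE,
                            contaminant = TRUE, rt_bounds = NULL,
                            boundary = 1) {
  rv_l <- if (transform_evidence) {
    goal_relevant_evidence(data$r_left, data$frame)
  } else data$r_left
  rv_r <- if (transform_evidence) {
    goal_relevant_evidence(data$r_right, data$frame)
  } else data$r_right
  g <- relative_gaze(data$dt_left_ms, data$dt_right_ms)
  P <- rv_l * g$g_left - rv_r * g$g_right
  Q <- rv_l * (1 - g$g_left) - rv_r * (1 - g$g_right)
  rt_ms <- data$rt_s * 1000
  right <- data$choice == "right"
  if (contaminant) {
    if (is.null(rt_bounds)) rt_bounds <- range(rt_ms)
    if (rt_bounds[1] >= rt_bounds[2]) rt_bounds <- rt_bounds + c(-1, 1)
    unif_dens <- 0.5 / (rt_bounds[2] - rt_bounds[1]) *
      (rt_ms >= rt_bounds[1] & rt_ms <= rt_bounds[2])
  }
  function(theta, w = 0.05) {
    nu <- theta[1]; gamma <- theta[2]; sigma <- theta[3]; tau <- theta[4]
    rstar_l <- P + gamma * Q
    R_l <- stats::plogis(tau * rstar_l)
    d_l <- nu * R_l
    d_r <- nu * (1 - R_l)
    d_c <- ifelse(right, d_r, d_l)
    d_o <- ifelse(right, d_l, d_r)
    f_c <- fpt_density(rt_ms, d_c, sigma, boundary)
    S_o <- fpt_cdf(rt_ms, d_o, sigma, boundary, lower.tail = FALSE)
    if (contaminant) {
      log((1 - w) * f_c * S_o + w * unif_dens)
    } else {
      log(f_c * S_o)
    }
  }
}

#' Fit the GLAM to one participant's trials
#'
#' Per-participant estimation of (nu, gamma, sigma, tau) under independent
#' uniform priors (nu ~ U(1e-10, 0.01), gamma ~ U(-1, 1), sigma ~
#' U(1e-10, 5), tau ~ U(0, 5)). Two modes:
#'
#' * `"map"`: bounded multi-start L-BFGS-B maximisation of the (log)
#'   posterior (= likelihood under the flat priors). Deterministic given the
#'   start set, and fast. A Laplace approximation around the optimum supplies
#'   the posterior draws used for WAIC.
#' * `"mcmc"`: component-wise adaptive random-walk Metropolis within the
#'   prior box (proposals outside the support are rejected, which is the
#'   correct Metropolis move under a uniform prior). The documented default
#'   mirrors the reference sampler settings (4 chains, 1000 tuning
#'   iterations, 2000 posterior draws per chain).
#'
#' Convergence is diagnosed with the split Gelman-Rubin statistic
#' (`|rhat - 1| < 0.05`) and the effective sample size (`ess > 100`) for all
#' four parameters; a failing fit is flagged (`converged = FALSE`), not an
#' error.
#'
#' Fitting is conventionally done on even-numbered trials only (see
#' [even_trials()]); this function fits whatever it is given.
#'
#' @param data One participant's trial tibble (one frame).
#' @param frame Optional frame filter applied to `data` first.
#' @param mode `"map"` or `"mcmc"`.
#' @param transform_evidence Use goal-relevant evidence (default TRUE); FALSE
#'   fits the frame-blind model on raw evidence.
#' @param contaminant_in_likelihood Include the 5% contaminant mixture inside
#'   the likelihood (default TRUE).
#' @param allow_negative_gamma Let gamma range over `[-1, 1]` (default) or
#'   restrict to `[0, 1]`.
#' @param chains,tune,draws MCMC settings (per chain).
#' @param laplace_draws Posterior draws from the Laplace approximation in
#'   MAP mode (for WAIC).
#' @param n_starts Number of L-BFGS-B starts in MAP mode.
#' @return An object of class `glam_fit`: list with `estimates` (posterior
#'   means, or MAP), `draws` (matrix with a `chain` attribute), `rhat`,
#'   `ess`, `waic` (list: `waic`, `lppd`, `p_waic`), `converged`,
#'   `n_divergences` (always 0 for this sampler), `mode`, `nll`,
#'   `trial_index` of the fitted trials.
#' @export
fit_glam <- function(data, frame = NULL,
                     mode = c("map", "mcmc"),
                     transform_evidence = TRUE,
                     contaminant_in_likelihood = TRUE,
                     allow_negative_gamma = TRUE,
                     chains = 4, tune = 1000, draws = 2000,
                     laplace_draws = 200, n_starts = 5) {
  mode <- match.arg(mode)
  if (!is.null(frame)) data <- data[data$frame == frame, ]
  stopifnot(nrow(data) >= 10)
  bounds <- glam_prior_bounds(allow_negative_gamma)
  ll_fun <- make_loglik_fun(data, transform_evidence,
                            contaminant = contaminant_in_likelihood)
  w <- if (contaminant_in_likelihood) 0.05 else 0
  obj <- function(theta) {
    v <- -sum(ll_fun(theta, w))
    if (!is.finite(v)) 1e10 else v
  }
  map <- map_optimise(obj, bounds, n_starts)
  if (mode == "map") {
    dr <- laplace_sample(obj, map$par, bounds, laplace_draws)
    ll_mat <- t(apply(dr, 1, ll_fun, w = w))
    res <- list(
      estimates = map$par, draws = dr,
      rhat = stats::setNames(rep(1, 4), names(map$par)),
      ess = stats::setNames(rep(Inf, 4), names(map$par)),
      waic = waic_from_loglik(ll_mat),
      converged = TRUE, n_divergences = 0L, mode = "map",
      nll = map$value, trial_index = data$trial_index
    )
  } else {
    mc <- metropolis_chains(ll_fun, w, map$par, bounds, chains, tune, draws)
    est <- colMeans(mc$draws)
    rhat <- split_rhat(mc$draws, mc$chain)
    ess <- ess_by_param(mc$draws, mc$chain)
    res <- list(
      estimates = est, draws = structure(mc$draws, chain = mc$chain),
      rhat = rhat, ess = ess,
      waic = waic_from_loglik(mc$loglik),
      converged = all(abs(rhat - 1) < 0.05) && all(ess > 100),
      n_divergences = 0L, mode = "mcmc",
      nll = obj(est), trial_index = data$trial_index
    )
  }
  class(res) <- "glam_fit"
  res
}

#' @export
print.glam_fit <- function(x, ...) {
  cat("<glam_fit> mode:", x$mode,
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  est <- x$estimates
  for (p in names(est)) {
    cat(sprintf("  %-6s %.6g  (rhat %.3f, ess %.0f)\n",
                p, est[[p]], x$rhat[[p]], x$ess[[p]]))
  }
  cat(sprintf("  WAIC %.2f  (lppd %.2f, p_waic %.2f), nll %.2f on %d trials\n",
              x$waic$waic, x$waic$lppd, x$waic$p_waic, x$nll,
              length(x$trial_index)))
  invisible(x)
}

map_optimise <- function(obj, bounds, n_starts) {
  lo <- bounds$lower; hi <- bounds$upper
  # diverse deterministic starts across the prior box
  starts <- list(
    c(nu = 1e-3, gamma = 0.3, sigma = 0.02, tau = 1),
    c(nu = 5e-4, gamma = 0.0, sigma = 0.05, tau = 0.5),
    c(nu = 2e-3, gamma = 0.6, sigma = 0.01, tau = 2),
    c(nu = 5e-3, gamma = -0.3, sigma = 0.1, tau = 0.2),
    c(nu = 2e-4, gamma = 0.9, sigma = 0.005, tau = 4)
  )[seq_len(max(1, min(n_starts, 5)))]
  starts <- lapply(starts, function(s) pmin(pmax(s, lo + 1e-9), hi - 1e-9))
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(
      s, obj, method = "L-BFGS-B", lower = lo + 1e-12, upper = hi,
      control = list(parscale = c(1e-3, 0.5, 0.02, 1), maxit = 500)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all MAP optimisation starts failed")
  names(best$par) <- c("nu", "gamma", "sigma", "tau")
  best
}

laplace_sample <- function(obj, par, bounds, n_draws) {
  h <- try(stats::optimHess(par, obj), silent = TRUE)
  cov <- NULL
  if (!inherits(h, "try-error")) {
    cov <- try(solve(h), silent = TRUE)
    if (inherits(cov, "try-error") || any(!is.finite(cov)) ||
        any(diag(cov) <= 0)) cov <- NULL
  }
  if (is.null(cov)) {
    # fall back to a small diagonal around the optimum
    cov <- diag((0.05 * pmax(abs(par), c(1e-4, 0.1, 1e-3, 0.1)))^2)
  }
  ch <- chol((cov + t(cov)) / 2)
  out <- matrix(NA_real_, n_draws, 4,
                dimnames = list(NULL, c("nu", "gamma", "sigma", "tau")))
  filled <- 0L
  for (attempt in 1:50) {
    need <- n_draws - filled
    if (need <= 0L) break
    cand <- matrix(rep(par, each = need), need, 4) +
      matrix(stats::rnorm(need * 4), need, 4) %*% ch
    ok <- apply(cand, 1, function(x) all(x > bounds$lower & x < bounds$upper))
    k <- sum(ok)
    if (k > 0) {
      out[filled + seq_len(k), ] <- cand[ok, , drop = FALSE]
      filled <- filled + k
    }
  }
  if (filled < n_draws) {
    # extremely tight boundary posterior: pad with the optimum itself
    out[(filled + 1):n_draws, ] <- matrix(rep(par, each = n_draws - filled),
                                          n_draws - filled, 4)
  }
  out
}

metropolis_chains <- function(ll_fun, w, init, bounds, chains, tune, draws) {
  lo <- bounds$lower; hi <- bounds$upper
  npar <- 4L
  all_draws <- vector("list", chains)
  all_ll <- vector("list", chains)
  for (ch in seq_len(chains)) {
    s <- 0.1 * (hi - lo) / 10   # initial proposal SDs
    theta <- pmin(pmax(init * stats::runif(npar, 0.8, 1.25) +
                         c(0, stats::rnorm(1, 0, 0.05), 0, 0),
                       lo + 1e-9), hi - 1e-9)
    ll_vec <- ll_fun(theta, w)
    lp <- sum(ll_vec)
    if (!is.finite(lp)) { theta <- init; ll_vec <- ll_fun(theta, w); lp <- sum(ll_vec) }
    acc <- numeric(npar); prop <- numeric(npar)
    keep <- matrix(NA_real_, draws, npar)
    keep_ll <- matrix(NA_real_, draws, length(ll_vec))
    for (it in seq_len(tune + draws)) {
      for (j in seq_len(npar)) {
        cand <- theta
        cand[j] <- theta[j] + stats::rnorm(1, 0, s[j])
        prop[j] <- prop[j] + 1
        if (cand[j] <= lo[j] || cand[j] >= hi[j]) next
        cand_ll <- ll_fun(cand, w)
        cand_lp <- sum(cand_ll)
        if (is.finite(cand_lp) &&
            log(stats::runif(1)) < cand_lp - lp) {
          theta <- cand; lp <- cand_lp; ll_vec <- cand_ll
          acc[j] <- acc[j] + 1
        }
      }
      if (it <= tune && it %% 25L == 0L) {
        rate <- acc / pmax(prop, 1)
        s <- s * exp(1.5 * (rate - 0.44))
        s <- pmin(pmax(s, 1e-8 * (hi - lo)), hi - lo)
        acc[] <- 0; prop[] <- 0
      }
      if (it > tune) {
        keep[it - tune, ] <- theta
        keep_ll[it - tune, ] <- ll_vec
      }
    }
    colnames(keep) <- c("nu", "gamma", "sigma", "tau")
    all_draws[[ch]] <- keep
    all_ll[[ch]] <- keep_ll
  }
  list(draws = do.call(rbind, all_draws),
       chain = rep(seq_len(chains), each = draws),
       loglik = do.call(rbind, all_ll))
}

#' WAIC from a pointwise log-likelihood matrix
#'
#' `lppd = sum_t log mean_s exp(ll[s, t])`, `p_waic = sum_t var_s(ll[s, t])`,
#' `waic = -2 (lppd - p_waic)` (deviance scale; lower is better).
#'
#' @param ll Matrix of log-likelihoods, draws x observations.
#' @return List with `waic`, `lppd`, `p_waic`, `pointwise` (per observation).
#' @export
waic_from_loglik <- function(ll) {
  stopifnot(is.matrix(ll), nrow(ll) >= 2)
  m <- apply(ll, 2, max)
  lppd_t <- m + log(colMeans(exp(sweep(ll, 2, m)))) # log-mean-exp, stabilised
  p_t <- apply(ll, 2, stats::var)
  elpd_t <- lppd_t - p_t
  list(waic = -2 * sum(elpd_t), lppd = sum(lppd_t), p_waic = sum(p_t),
       pointwise = -2 * elpd_t)
}

split_rhat <- function(draws, chain) {
  vapply(colnames(draws), function(p) {
    x <- draws[, p]
    halves <- unlist(lapply(split(x, chain), function(v) {
      h <- length(v) %/% 2L
      list(v[seq_len(h)], v[h + seq_len(h)])
    }), recursive = FALSE)
    m <- length(halves); n <- length(halves[[1]])
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, stats::var, numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    vhat <- (n - 1) / n * W + B / n
    if (W <= 0) return(1)
    sqrt(vhat / W)
  }, numeric(1))
}

# Geyer initial-positive-sequence effective sample size, summed over chains
ess_by_param <- function(draws, chain) {
  vapply(colnames(draws), function(p) {
    sum(vapply(split(draws[, p], chain), function(x) {
      n <- length(x)
      if (stats::var(x) == 0) return(1)
      rho <- stats::acf(x, lag.max = min(n - 2L, 500L), plot = FALSE,
                        demean = TRUE)$acf[-1]
      # sum of adjacent pairs until a pair goes non-positive
      pair <- rho[seq(1, length(rho) - 1, by = 2)] +
        rho[seq(2, length(rho), by = 2)]
      neg <- which(pair <= 0)
      k <- if (length(neg) > 0) neg[1] - 1L else length(pair)
      tau_int <- 1 + 2 * sum(rho[seq_len(2 * k)])
      max(1, n / max(tau_int, 1e-3))
    }, numeric(1)))
  }, numeric(1))
}

#' Compare goal-relevant and frame-blind fits by WAIC
#'
#' Both fits must cover the identical trial set. Lower WAIC wins.
#'
#' @param fit_goal_relevant,fit_untransformed `glam_fit` objects.
#' @return A list with `waic_goal_relevant`, `waic_untransformed`,
#'   `waic_difference` (goal-relevant minus untransformed; negative favours
#'   the goal-relevant model) and `preferred`.
#' @export
compare_models <- function(fit_goal_relevant, fit_untransformed) {
  if (!identical(fit_goal_relevant$trial_index,
                 fit_untransformed$trial_index)) {
    stop("fits were computed on different trial sets")
  }
  d <- fit_goal_relevant$waic$waic - fit_untransformed$waic$waic
  list(
    waic_goal_relevant = fit_goal_relevant$waic$waic,
    waic_untransformed = fit_untransformed$waic$waic,
    waic_difference = d,
    preferred = if (d < 0) "goal_relevant" else "untransformed"
  )
}

#' Drop RT outlier trials
#'
#' Removes trials with RT more than 3 SD above/below the participant mean or
#' above 20 s (the perceptual-fit filtering rule).
#'
#' @param data Trial tibble with `participant_id` and `rt_s`.
#' @return Filtered tibble.
#' @export
filter_rt_outliers <- function(data) {
  dplyr::filter(
    dplyr::group_by(data, .data$participant_id),
    abs(.data$rt_s - mean(.data$rt_s)) <= 3 * stats::sd(.data$rt_s),
    .data$rt_s <= 20
  ) |> dplyr::ungroup()
}

#' Parameter-recovery study
#'
#' Simulates synthetic participants at each row of a parameter grid, fits
#' them back (MAP mode by default) and tabulates true versus recovered
#' parameters.
#'
#' @param param_grid Tibble/data.frame with columns `nu`, `gamma`, `sigma`,
#'   `tau` (one row per grid cell).
#' @param n_trials Trials per synthetic participant (default 240).
#' @param n_participants Participants per grid cell.
#' @param experiment `"value"` or `"perceptual"`.
#' @param frame Frame to simulate (default `"like"`).
#' @param mode Fitting mode passed to [fit_glam()].
#' @param seed Integer seed.
#' @param gaze_cfg A [gaze_config()] used by the generator.
#' @return A tibble with one row per (cell, participant, parameter):
#'   `cell`, `participant`, `param`, `true`, `recovered`.
#' @export
recovery_study <- function(param_grid, n_trials = 240, n_participants = 1,
                           experiment = "value", frame = "like",
                           mode = "map", seed = 1,
                           gaze_cfg = gaze_config()) {
  bounds <- glam_prior_bounds()
  rows <- list()
  for (cell in seq_len(nrow(param_grid))) {
    pg <- param_grid[cell, ]
    stopifnot(all(unlist(pg[c("nu", "gamma", "sigma", "tau")]) >=
                    bounds$lower - 1e-12))
    params <- glam_params(pg$nu, pg$gamma, pg$sigma, pg$tau)
    for (pp in seq_len(n_participants)) {
      set.seed((seed + 7919L * (cell * 100L + pp)) %% .Machine$integer.max)
      dat <- simulate_participant(params, n_trials = n_trials,
                                  experiment = experiment, frame = frame,
                                  gaze_cfg = gaze_cfg,
                                  participant_id = sprintf("c%02dp%02d", cell, pp))
      fit <- fit_glam(dat, mode = mode)
      for (par in c("nu", "gamma", "sigma", "tau")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          cell = cell, participant = pp, param = par,
          true = pg[[par]], recovered = unname(fit$estimates[[par]])
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
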