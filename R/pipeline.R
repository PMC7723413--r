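#' Run the full analysis pipeline on synthetic data
#'
#' End-to-end driver: generates a synthetic dataset, fits the GLAM per
#' participant and frame on even-numbered trials, produces out-of-sample
#' behavioural predictions and balance-of-evidence simulations on
#' odd-numbered trials (with and without the gaze bias), runs the
#' behavioural analyses, verifies the optimal-sampling propositions, and
#' writes every table to `out_dir` together with a manifest recording the
#' seed and an MD5 checksum per output.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_participants Number of synthetic participants (default 4 for a
#'   quick demonstration run; 31 reproduces the value-experiment scale).
#' @param experiment `"value"` or `"perceptual"`.
#' @param params Generating [glam_params()] (shared across participants).
#' @param fit_mode `"map"` (default) or `"mcmc"`.
#' @param seed Master seed; recorded in the manifest.
#' @param config A [sim_config()].
#' @param gaze_cfg A [gaze_config()].
#' @return Invisibly, a list with the in-memory results (`dataset`, `fits`,
#'   `predictions`, `delta_e`, `delta_e_nobias`, `choice_reg`,
#'   `delta_e_reg`, `propositions`, `manifest`).
#' @export
run_pipeline <- function(out_dir, n_participants = 4,
                         experiment = c("value", "perceptual"),
                         params = glam_params(nu = 1e-3, gamma = 0.3,
                                              sigma = 0.02, tau = 1),
                         fit_mode = "map", seed = 1,
                         config = sim_config(n_reps_behaviour = 10),
                         gaze_cfg = gaze_config()) {
  experiment <- match.arg(experiment)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  frames <- if (experiment == "value") c("like", "dislike") else c("most", "fewest")

  ds <- generate_dataset(n_participants, experiment, params,
                         gaze_cfg = gaze_cfg, config = config, seed = seed)
  write_trials(ds$trials, file.path(out_dir, "trials.csv"))
  write_fixations(ds$fixations, file.path(out_dir, "fixations.csv"))

  fits <- list(); preds <- list(); de <- list(); de_nb <- list()
  pids <- unique(ds$trials$participant_id)
  for (i in seq_along(pids)) {
    pid <- pids[i]
    for (fr in frames) {
      set.seed((seed + 104729L * i + match(fr, frames)) %% .Machine$integer.max)
      d_p <- ds$trials[ds$trials$participant_id == pid & ds$trials$frame == fr, ]
      if (experiment == "perceptual") d_p <- filter_rt_outliers(d_p)
      fit <- fit_glam(even_trials(d_p), mode = fit_mode)
      fits[[paste(pid, fr)]] <- fit
      est <- fit$estimates
      p_hat <- glam_params(est["nu"], est["gamma"], est["sigma"], est["tau"])
      write_glam_params(p_hat, file.path(out_dir,
        sprintf("params_%s_%s.json", pid, fr)))
      odd <- odd_trials(d_p)
      preds[[paste(pid, fr)]] <- out_of_sample_predict(odd, p_hat, config)
      de[[paste(pid, fr)]] <- delta_e_table(odd, p_hat, config)
      nb <- config; nb$no_gaze_bias <- TRUE
      de_nb[[paste(pid, fr)]] <- delta_e_table(odd, p_hat, nb)
    }
  }
  predictions <- dplyr::bind_rows(preds)
  delta_e <- dplyr::bind_rows(de)
  delta_e_nobias <- dplyr::bind_rows(de_nb)
  readr::write_csv(predictions, file.path(out_dir, "oos_predictions.csv"),
                   progress = FALSE)
  readr::write_csv(delta_e, file.path(out_dir, "delta_e.csv"), progress = FALSE)
  readr::write_csv(delta_e_nobias, file.path(out_dir, "delta_e_nobias.csv"),
                   progress = FALSE)

  choice_reg <- lapply(frames, function(fr) {
    choice_regression(ds$trials[ds$trials$frame == fr, ])
  })
  names(choice_reg) <- frames
  readr::write_csv(
    dplyr::bind_rows(lapply(frames, function(fr) {
      dplyr::mutate(choice_reg[[fr]]$group, frame = fr, .before = 1)
    })),
    file.path(out_dir, "choice_regression.csv"), progress = FALSE)

  delta_e_reg <- lapply(frames, function(fr) {
    confidence_regression(delta_e[delta_e$frame == fr, ])
  })
  names(delta_e_reg) <- frames
  readr::write_csv(
    dplyr::bind_rows(lapply(frames, function(fr) {
      dplyr::mutate(delta_e_reg[[fr]], frame = fr, .before = 1)
    })),
    file.path(out_dir, "delta_e_regression.csv"), progress = FALSE)

  set.seed(seed)
  props <- verify_propositions(n_values = 2:4, n_configs = 20)
  readr::write_csv(props, file.path(out_dir, "propositions.csv"),
                   progress = FALSE)

  files <- list.files(out_dir, pattern = "\\.(csv|json)$")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    seed = seed, n_participants = n_participants, experiment = experiment
  )
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"),
                   progress = FALSE)
  invisible(list(dataset = ds, fits = fits, predictions = predictions,
                 delta_e = delta_e, delta_e_nobias = delta_e_nobias,
                 choice_reg = choice_reg, delta_e_reg = delta_e_reg,
                 propositions = props, manifest = manifest))
}
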