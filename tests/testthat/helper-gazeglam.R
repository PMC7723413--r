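# shared fixtures built in code

quick_params <- function(...) {
  glam_params(nu = 1e-3, gamma = 0.3, sigma = 0.02, tau = 1, ...)
}

# a tiny deterministic trial table covering both frames
tiny_trials <- function(n = 12, participant_id = "p01", frame = "like") {
  set.seed(99)
  tibble::tibble(
    participant_id = participant_id, experiment = "value", frame = frame,
    block = 1L, trial_index = seq_len(n),
    r_left = round(seq(0.2, 2.8, length.out = n), 2),
    r_right = round(rev(seq(0.4, 2.9, length.out = n)), 2),
    dt_left_ms = seq(400, 1500, length.out = n),
    dt_right_ms = rev(seq(300, 1400, length.out = n)),
    rt_s = (seq(400, 1500, length.out = n) + rev(seq(300, 1400, length.out = n))) / 1000,
    choice = rep(c("left", "right"), length.out = n),
    confidence = rep(5, n)
  )
}
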