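#' Per-bin gaze matrix
#'
#' Segments each trial's fixation sequence into `bin_ms` samples over the
#' first `window_ms` after stimulus onset. Entry (trial, bin) is 1 when gaze
#' is on the right option at the bin's centre, 0 when on the left and NA
#' when no fixation covers it (trial over, or between fixations).
#'
#' @param trials Trial tibble.
#' @param fixations Long fixation tibble.
#' @param bin_ms Bin width (default 10 ms).
#' @param window_ms Analysis window (default 2000 ms).
#' @return A matrix `n_trials x n_bins`, rows aligned with `trials`, with
#'   bin centre times (ms) as an attribute `"time_ms"`.
#' @export
gaze_bin_matrix <- function(trials, fixations, bin_ms = 10, window_ms = 2000) {
  centres <- seq(bin_ms / 2, window_ms - bin_ms / 2, by = bin_ms)
  n_bins <- length(centres)
  M <- matrix(NA_real_, nrow(trials), n_bins)
  key_t <- paste(trials$participant_id, trials$trial_index)
  fx_split <- split(fixations, paste(fixations$participant_id,
                                     fixations$trial_index))
  for (i in seq_len(nrow(trials))) {
    fx <- fx_split[[key_t[i]]]
    if (is.null(fx) || nrow(fx) == 0L) next
    ends <- fx$onset_ms + fx$duration_ms
    idx <- findInterval(centres, fx$onset_ms)
    ok <- idx >= 1L & centres <= ends[pmax(idx, 1L)]
    M[i, ok] <- as.numeric(fx$side[idx[ok]] == "right")
  }
  attr(M, "time_ms") <- centres
  M
}

# column-wise Pearson correlation between a 0/1-with-NA matrix and a vector
cor_bins <- function(M, dv, min_trials = 2L) {
  O <- !is.na(M)
  X <- M; X[!O] <- 0
  n <- colSums(O)
  sx <- colSums(X)
  sxx <- sx                      # X is 0/1 so X^2 = X
  sy <- drop(crossprod(O, dv))
  syy <- drop(crossprod(O, dv^2))
  sxy <- drop(crossprod(X, dv))
  num <- n * sxy - sx * sy
  den <- sqrt(pmax(n * sxx - sx^2, 0) * pmax(n * syy - sy^2, 0))
  r <- ifelse(n >= min_trials & den > 0, num / den, NA_real_)
  list(r = r, n = n)
}

#' Fixation time-series correlation
#'
#' For each 10 ms bin within the first 2 s of the trials, the Pearson
#' correlation across trials between instantaneous gaze position (0 = left,
#' 1 = right) and the raw evidence difference (right minus left). Trials are
#' pooled over participants; no temporal normalisation is applied. Bins
#' covered by fewer than two trials, or with zero variance, are reported as
#' NA.
#'
#' @param trials Trial tibble (filter to one frame for a per-frame series).
#' @param fixations Long fixation tibble.
#' @param bin_ms,window_ms Binning parameters.
#' @return Tibble: `time_ms` (bin centre), `r`, `n_trials`.
#' @export
fixation_timeseries <- function(trials, fixations, bin_ms = 10,
                                window_ms = 2000) {
  M <- gaze_bin_matrix(trials, fixations, bin_ms, window_ms)
  dv <- trials$r_right - trials$r_left
  cb <- cor_bins(M, dv)
  tibble::tibble(time_ms = attr(M, "time_ms"), r = cb$r, n_trials = cb$n)
}

#' Permutation test for the between-frame correlation difference
#'
#' Computes the per-bin gaze-evidence correlation separately for two frames
#' and tests the difference at each bin against a null built by shuffling
#' the frame labels of whole trials (`n_perm` label permutations; the
#' exchangeable-trials null). An alternative mode shuffles instantaneous
#' samples within each bin (`shuffle = "instantaneous"`). Per-bin p-values
#' are corrected with Benjamini-Hochberg FDR at `alpha`, and bins count as
#' significant only inside runs of at least `min_run` consecutive
#' significant bins. Bins with fewer than `min_trials` contributing trials
#' in either frame are reported but never flagged.
#'
#' @param trials Trial tibble containing both frames.
#' @param fixations Long fixation tibble.
#' @param frames Length-2 character: the two frames to contrast.
#' @param n_perm Number of permutations (default 200; below 100 a warning
#'   about p-value resolution is emitted).
#' @param alpha FDR level (default 0.01).
#' @param min_run Minimum run length in bins (default 6, i.e. 60 ms).
#' @param bin_ms,window_ms Binning parameters.
#' @param min_trials Minimum trials per frame per bin for flag eligibility.
#' @param shuffle `"labels"` (default) or `"instantaneous"`.
#' @return Tibble: `time_ms`, `r_frame1`, `r_frame2`, `diff`, `n_frame1`,
#'   `n_frame2`, `p`, `q`, `significant`.
#' @export
permutation_frame_test <- function(trials, fixations, frames,
                                   n_perm = 200, alpha = 0.01, min_run = 6,
                                   bin_ms = 10, window_ms = 2000,
                                   min_trials = 10,
                                   shuffle = c("labels", "instantaneous")) {
  shuffle <- match.arg(shuffle)
  stopifnot(length(frames) == 2)
  if (n_perm < 100) warning("n_perm < 100: p-value resolution is coarse")
  tr <- trials[trials$frame %in% frames, ]
  M <- gaze_bin_matrix(tr, fixations, bin_ms, window_ms)
  dv <- tr$r_right - tr$r_left
  lab <- tr$frame
  diff_of <- function(labels) {
    c1 <- cor_bins(M[labels == frames[1], , drop = FALSE],
                   dv[labels == frames[1]])
    c2 <- cor_bins(M[labels == frames[2], , drop = FALSE],
                   dv[labels == frames[2]])
    list(d = c1$r - c2$r, c1 = c1, c2 = c2)
  }
  obs <- diff_of(lab)
  n_bins <- ncol(M)
  exceed <- integer(n_bins)
  valid_perm <- integer(n_bins)
  for (b in seq_len(n_perm)) {
    if (shuffle == "labels") {
      d_p <- diff_of(sample(lab))$d
    } else {
      Mp <- apply(M, 2, sample)  # shuffle instantaneous samples within bins
      c1 <- cor_bins(Mp[lab == frames[1], , drop = FALSE], dv[lab == frames[1]])
      c2 <- cor_bins(Mp[lab == frames[2], , drop = FALSE], dv[lab == frames[2]])
      d_p <- c1$r - c2$r
    }
    ok <- is.finite(d_p) & is.finite(obs$d)
    exceed[ok] <- exceed[ok] + (abs(d_p[ok]) >= abs(obs$d[ok]))
    valid_perm[ok] <- valid_perm[ok] + 1L
  }
  p <- ifelse(valid_perm > 0, (1 + exceed) / (1 + valid_perm), NA_real_)
  eligible <- is.finite(p) & obs$c1$n >= min_trials & obs$c2$n >= min_trials
  q <- rep(NA_real_, n_bins)
  q[eligible] <- stats::p.adjust(p[eligible], method = "BH")
  sig_raw <- !is.na(q) & q <= alpha
  significant <- flag_runs(sig_raw, min_run)
  tibble::tibble(
    time_ms = attr(M, "time_ms"),
    r_frame1 = obs$c1$r, r_frame2 = obs$c2$r, diff = obs$d,
    n_frame1 = obs$c1$n, n_frame2 = obs$c2$n,
    p = p, q = q, significant = significant
  )
}

# keep only TRUE-runs of length >= min_run
flag_runs <- function(x, min_run) {
  r <- rle(x)
  r$values <- r$values & r$lengths >= min_run
  inverse.rle(r)
}
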