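#' GLAM parameter set
#'
#' Bundles the four free parameters of the gaze-weighted linear accumulator
#' model together with the fixed decision boundary and the weight of the
#' contaminant (random choice / uniform RT) mixture component.
#'
#' The accumulator operates on a millisecond time base: `nu` is the drift
#' scaling per ms, and `sigma` the diffusion noise SD per sqrt(ms). With the
#' boundary fixed at 1 the mean first-passage time of an accumulator with
#' scaled evidence R is `1 / (nu * R)` ms.
#'
#' @param nu Drift scaling (> 0), evidence units per ms.
#' @param gamma Gaze-bias weight in `[-1, 1]`. `gamma = 1` removes the gaze
#'   asymmetry entirely; `gamma < 1` discounts the unattended item;
#'   `gamma < 0` lets unattended evidence leak.
#' @param sigma Diffusion noise SD (> 0), evidence units per sqrt(ms).
#' @param tau Evidence-scaling sensitivity (>= 0) of the logistic transform;
#'   `tau = 0` makes the accumulators insensitive to relative evidence.
#' @param boundary Decision threshold, fixed at 1.
#' @param contaminant_rate Mixture weight in `[0, 1)` of the random-choice /
#'   uniform-RT process (default 0.05).
#'
#' @return An object of class `glam_params` (a named list).
#' @examples
#' glam_params(nu = 0.001, gamma = 0.3, sigma = 0.02, tau = 1)
#' @export
glam_params <- function(nu, gamma, sigma, tau, boundary = 1,
                        contaminant_rate = 0.05) {
  p <- list(nu = nu, gamma = gamma, sigma = sigma, tau = tau,
            boundary = boundary, contaminant_rate = contaminant_rate)
  validate_glam_params(p)
  structure(p, class = "glam_params")
}

validate_glam_params <- function(p) {
  stopifnot(
    is.numeric(p$nu), length(p$nu) == 1L, p$nu > 0,
    is.numeric(p$gamma), length(p$gamma) == 1L, p$gamma >= -1, p$gamma <= 1,
    is.numeric(p$sigma), length(p$sigma) == 1L, p$sigma > 0,
    is.numeric(p$tau), length(p$tau) == 1L, p$tau >= 0,
    is.numeric(p$boundary), length(p$boundary) == 1L, p$boundary == 1,
    is.numeric(p$contaminant_rate), length(p$contaminant_rate) == 1L,
    p$contaminant_rate >= 0, p$contaminant_rate < 1
  )
  invisible(p)
}

#' @export
print.glam_params <- function(x, ...) {
  cat("<glam_params>\n")
  cat(sprintf("  nu      = %g (drift scaling, 1/ms)\n", x$nu))
  cat(sprintf("  gamma   = %g (gaze bias)\n", x$gamma))
  cat(sprintf("  sigma   = %g (noise SD, 1/sqrt(ms))\n", x$sigma))
  cat(sprintf("  tau     = %g (evidence scaling)\n", x$tau))
  cat(sprintf("  boundary = %g, contaminant = %g\n",
              x$boundary, x$contaminant_rate))
  invisible(x)
}

#' Uniform prior bounds used for fitting
#'
#' The prior support for each free parameter: nu ~ U(1e-10, 0.01),
#' gamma ~ U(-1, 1) (or U(0, 1) when `allow_negative_gamma = FALSE`),
#' sigma ~ U(1e-10, 5), tau ~ U(0, 5).
#'
#' @param allow_negative_gamma Allow gamma below zero (default TRUE).
#' @return A list with `lower` and `upper` named numeric vectors.
#' @export
glam_prior_bounds <- function(allow_negative_gamma = TRUE) {
  list(
    lower = c(nu = 1e-10, gamma = if (allow_negative_gamma) -1 else 0,
              sigma = 1e-10, tau = 0),
    upper = c(nu = 0.01, gamma = 1, sigma = 5, tau = 5)
  )
}

#' Write and read GLAM parameters as JSON
#'
#' @param params A [glam_params()] object.
#' @param path File path.
#' @return `write_glam_params()` returns `path` invisibly;
#'   `read_glam_params()` returns a [glam_params()] object.
#' @export
write_glam_params <- function(params, path) {
  validate_glam_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_glam_params
#' @export
read_glam_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  glam_params(nu = p$nu, gamma = p$gamma, sigma = p$sigma, tau = p$tau,
              boundary = p$boundary, contaminant_rate = p$contaminant_rate)
}
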