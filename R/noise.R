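#' Measurement-noise specification
#'
#' Magnitude MRI noise is Rician: independent Gaussian noise of standard
#' deviation `sigma` on the real and imaginary channels, followed by the
#' magnitude operation. `sigma` is set as `reference / snr`; when
#' `reference` is `NULL` it is taken at render time as the mean noiseless
#' cycle-1 signal over non-zero voxels. A plain additive Gaussian model is
#' available for analytic checks, and `"none"` disables noise.
#'
#' @param model `"rician"`, `"gaussian"` or `"none"`.
#' @param snr Signal-to-noise ratio (> 0; `Inf` disables noise).
#' @param reference Reference signal level defining `sigma = reference/snr`,
#'   or `NULL` to derive it from the data.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("rician", "gaussian", "none"),
                       snr = Inf, reference = NULL) {
  model <- match.arg(model)
  if (model != "none" && (!is.numeric(snr) || snr <= 0))
    .stopf("snr must be > 0")
  structure(list(model = model, snr = snr, reference = reference),
            class = "noise_spec")
}

#' Add measurement noise to a magnitude image stack
#'
#' @param images Numeric array of noiseless magnitudes.
#' @param noise A [noise_spec()] object.
#' @param seed Integer seed for reproducibility; `NULL` leaves the RNG
#'   state untouched.
#' @return Array of the same shape. With `model = "none"` or infinite SNR
#'   the input is returned unchanged.
#' @export
add_noise <- function(images, noise = noise_spec(), seed = NULL) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$model == "none" || is.infinite(noise$snr)) return(images)
  ref <- noise$reference
  if (is.null(ref)) ref <- mean(images[images > 0])
  sigma <- ref / noise$snr
  if (!is.null(seed)) set.seed(seed)
  n <- length(images)
  out <- switch(noise$model,
    rician = sqrt((images + stats::rnorm(n, sd = sigma))^2 +
                  stats::rnorm(n, sd = sigma)^2),
    gaussian = images + stats::rnorm(n, sd = sigma)
  )
  array(out, dim = dim(images))
}

#' Estimate the noise level from a signal-free background patch
#'
#' In the background the Rician magnitude reduces to a Rayleigh variate
#' with `E[v^2] = 2 sigma^2`, so `sigma` is estimated as
#' `sqrt(mean(v^2)/2)`; for the Gaussian model the plain standard deviation
#' is used.
#'
#' @param values Background voxel values.
#' @param model `"rician"` or `"gaussian"`.
#' @return Estimated `sigma`.
#' @export
estimate_noise_sigma <- function(values, model = c("rician", "gaussian")) {
  model <- match.arg(model)
  if (model == "rician") sqrt(mean(values^2) / 2) else stats::sd(values)
}

#' Per-cycle signal-to-noise ratio of a rendered series
#'
#' SNR of cycle n is the mean signal inside `signal_roi` divided by the
#' standard deviation inside `noise_roi`, both pooled over repetitions.
#'
#' @param series A [render_dwi_series()] result.
#' @param signal_roi,noise_roi Logical matrices (or voxel index vectors) on
#'   the image grid; must be disjoint and non-empty.
#' @return Data frame with columns `cycle` and `snr`; `snr` is `Inf` (with a
#'   warning) for a noiseless series.
#' @export
measure_snr <- function(series, signal_roi, noise_roi) {
  stopifnot(inherits(series, "dwi_series"))
  d <- dim(series$data)
  sig_idx <- if (is.logical(signal_roi)) which(signal_roi) else as.integer(signal_roi)
  noi_idx <- if (is.logical(noise_roi)) which(noise_roi) else as.integer(noise_roi)
  if (length(sig_idx) == 0L || length(noi_idx) == 0L) .stopf("empty ROI")
  if (length(intersect(sig_idx, noi_idx)) > 0L) .stopf("ROIs must be disjoint")
  flat <- matrix(series$data, nrow = d[1] * d[2])  # voxel x (cycle, rep)
  ncyc <- d[3]
  snr <- vapply(seq_len(ncyc), function(n) {
    cols <- n + ncyc * (seq_len(d[4]) - 1L)
    mean(flat[sig_idx, cols]) / stats::sd(flat[noi_idx, cols])
  }, numeric(1))
  if (any(!is.finite(snr)))
    warning("zero noise variance: SNR unbounded", call. = FALSE)
  data.frame(cycle = seq_len(ncyc), snr = snr)
}
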