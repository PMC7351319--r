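#' Instrument model for a time-multiplexed point-scanning FLIm system
#'
#' Describes the digitization layout of a four-channel fluorescence lifetime
#' imaging instrument in which the four spectral bands (nominally CH1
#' 390 +/- 20 nm, CH2 470 +/- 14 nm, CH3 542 +/- 25 nm, CH4 629 +/- 26.5 nm)
#' are optically delayed and recorded as consecutive time windows of a single
#' digitized voltage trace.  The record starts with a signal-free baseline
#' segment used for background subtraction, followed by the four channel
#' windows of equal length.
#'
#' @param sampling_ns Digitizer sampling interval in ns (default 0.08, i.e.
#'   80 ps at 12.5 GS/s).
#' @param samples_per_channel Number of samples in each channel window.  The
#'   default (768) gives a 61.4 ns observation window per channel, long
#'   enough that decays up to ~8 ns are captured with negligible truncation.
#' @param baseline_samples Number of signal-free samples preceding CH1,
#'   used to estimate and subtract the DC background.
#' @param irf_fwhm_ns Full width at half maximum of the Gaussian instrument
#'   response function, ns.  Default 0.6 (sub-ns laser + detector response).
#' @param onset_ns Delay of the IRF peak from the start of each channel
#'   window, ns.  The pre-onset segment of each window is signal-free and is
#'   used for per-channel noise estimation.
#' @param noise_window_samples Number of leading samples of each channel
#'   window treated as signal-free for noise-sigma estimation.
#' @param noise_sigma Baseline additive noise sigma (volts) used where no
#'   signal-derived noise level applies.
#' @param background_level Constant DC offset (volts) added to every record.
#' @param frame_width,frame_height White-light video frame size in pixels.
#'
#' @return An object of class `flim_instrument`.
#' @export
flim_instrument <- function(sampling_ns = 0.08,
                            samples_per_channel = 768L,
                            baseline_samples = 64L,
                            irf_fwhm_ns = 0.6,
                            onset_ns = 3.2,
                            noise_window_samples = 24L,
                            noise_sigma = 0.002,
                            background_level = 0.05,
                            frame_width = 1280L,
                            frame_height = 720L) {
  stopifnot(sampling_ns > 0, samples_per_channel >= 16,
            baseline_samples >= 8, irf_fwhm_ns > 0,
            onset_ns >= 0, noise_window_samples >= 4,
            frame_width > 0, frame_height > 0)
  n_channels <- 4L
  samples_per_channel <- as.integer(samples_per_channel)
  baseline_samples <- as.integer(baseline_samples)
  # windows are consecutive and therefore disjoint and time-ordered
  window_starts <- baseline_samples + (seq_len(n_channels) - 1L) * samples_per_channel
  structure(list(
    sampling_ns = sampling_ns,
    samples_per_channel = samples_per_channel,
    baseline_samples = baseline_samples,
    n_channels = n_channels,
    window_starts = window_starts,      # 0-based sample offsets of each window
    record_length = baseline_samples + n_channels * samples_per_channel,
    irf_fwhm_ns = irf_fwhm_ns,
    onset_ns = onset_ns,
    noise_window_samples = as.integer(noise_window_samples),
    noise_sigma = noise_sigma,
    background_level = background_level,
    frame_width = as.integer(frame_width),
    frame_height = as.integer(frame_height),
    channel_bands_nm = list(CH1 = c(390, 20), CH2 = c(470, 14),
                            CH3 = c(542, 25), CH4 = c(629, 26.5))
  ), class = "flim_instrument")
}

#' @export
print.flim_instrument <- function(x, ...) {
  cat("FLIm instrument model\n",
      sprintf("  sampling: %.0f ps, %d samples/channel (%.1f ns window)\n",
              x$sampling_ns * 1000, x$samples_per_channel,
              x$samples_per_channel * x$sampling_ns),
      sprintf("  IRF FWHM: %.0f ps (Gaussian), onset %.2f ns into window\n",
              x$irf_fwhm_ns * 1000, x$onset_ns),
      sprintf("  record: %d samples (%d baseline + 4 x %d)\n",
              x$record_length, x$baseline_samples, x$samples_per_channel),
      sprintf("  frame: %d x %d px\n", x$frame_width, x$frame_height),
      sep = "")
  invisible(x)
}

#' Time grid of one channel window
#'
#' @param model A [flim_instrument()].
#' @return Numeric vector of times in ns starting at 0.
#' @export
channel_time_grid <- function(model) {
  (seq_len(model$samples_per_channel) - 1) * model$sampling_ns
}

#' Sampled Gaussian instrument response function
#'
#' Returns the IRF sampled on a channel window's time grid: a Gaussian of the
#' configured FWHM centred `onset_ns` after the window start, normalized to
#' unit sum so that convolution conserves signal area.
#'
#' @param model A [flim_instrument()].
#' @param fwhm_ns Optional FWHM override, ns.
#' @return Numeric vector of length `model$samples_per_channel`, nonnegative,
#'   unimodal, summing to 1.
#' @export
generate_irf <- function(model, fwhm_ns = model$irf_fwhm_ns) {
  if (fwhm_ns < model$sampling_ns) {
    stop("IRF FWHM (", fwhm_ns, " ns) is below the sampling interval (",
         model$sampling_ns, " ns): unresolvable IRF")
  }
  t <- channel_time_grid(model)
  sigma <- fwhm_ns / (2 * sqrt(2 * log(2)))
  irf <- exp(-0.5 * ((t - model$onset_ns) / sigma)^2)
  irf / sum(irf)
}
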