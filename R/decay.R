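#' Subtract the DC background from a raw record
#'
#' The digitizer record begins with a signal-free baseline segment preceding
#' the first channel window; its mean is taken as the DC background and
#' subtracted from the whole record.
#'
#' @param record Numeric vector, one digitized voltage trace.
#' @param model A [flim_instrument()] describing the record layout, or NULL
#'   when `baseline` is given explicitly.
#' @param baseline Optional integer indices of the baseline window (must
#'   precede all channel windows).
#' @return The background-subtracted record, with attribute `background`
#'   holding the removed level.
#' @export
subtract_background <- function(record, model = NULL, baseline = NULL) {
  stopifnot(is.numeric(record), all(is.finite(record)))
  if (is.null(baseline)) {
    stopifnot(inherits(model, "flim_instrument"))
    baseline <- seq_len(model$baseline_samples)
  }
  if (!is.null(model) && max(baseline) > model$window_starts[1]) {
    stop("baseline window overlaps a channel window")
  }
  bg <- mean(record[baseline])
  out <- record - bg
  attr(out, "background") <- bg
  out
}

#' Split a record into its four time-multiplexed channel waveforms
#'
#' @param record Background-subtracted record (numeric vector).
#' @param model A [flim_instrument()].
#' @return List of 4 numeric vectors (CH1..CH4), each of length
#'   `model$samples_per_channel`, on a zero-based time grid.
#' @export
demultiplex <- function(record, model) {
  stopifnot(inherits(model, "flim_instrument"))
  if (length(record) < model$record_length) {
    stop("record has ", length(record), " samples but the instrument layout ",
         "requires ", model$record_length)
  }
  lapply(seq_len(model$n_channels), function(k) {
    s <- model$window_starts[k]
    as.numeric(record[(s + 1):(s + model$samples_per_channel)])
  })
}

#' Estimate the signal-to-noise ratio of a channel waveform
#'
#' SNR in dB is defined as `20 * log10(peak amplitude / noise sigma)` where
#' the noise sigma is the standard deviation of a signal-free segment of the
#' waveform (by default the pre-onset samples at the start of the channel
#' window).
#'
#' @param waveform Background-subtracted channel waveform.
#' @param noise_window Indices of the signal-free segment.
#' @param cap Value returned (with attribute `capped = TRUE`) when the noise
#'   sigma is exactly zero.
#' @return SNR in dB.
#' @export
estimate_snr <- function(waveform, noise_window = seq_len(24L), cap = 120) {
  stopifnot(length(waveform) > max(noise_window))
  sigma <- stats::sd(waveform[noise_window])
  peak <- max(waveform)
  if (sigma == 0) {
    out <- cap
    attr(out, "capped") <- TRUE
    return(out)
  }
  20 * log10(max(peak, 0) / sigma)
}
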