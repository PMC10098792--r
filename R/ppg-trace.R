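#' Construct a PPG trace
#'
#' A `ppg_trace` holds one wavelength channel's uniformly sampled
#' photoplethysmogram: the sample vector, the sampling rate, the channel
#' label and the time offset of the first sample.
#'
#' @param samples Numeric vector of waveform samples (arbitrary units). All
#'   values must be finite and there must be at least two of them.
#' @param sampling_rate Sampling frequency in Hz (default 60, the rate of the
#'   simulated sensor).
#' @param channel Wavelength channel label, one of `"B"`, `"G"`, `"R"`,
#'   `"NIR"`.
#' @param t0 Time of the first sample in seconds relative to the start of
#'   the cuff measurement (default 0).
#'
#' @return An object of class `ppg_trace`.
#' @seealso [generate_pulse_train()], [detect_beats()]
#' @export
#' @examples
#' tr <- ppg_trace(1 + 0.01 * sin(2 * pi * seq(0, 5, by = 1 / 60)), 60, "NIR")
#' tr
ppg_trace <- function(samples, sampling_rate = 60, channel = "NIR", t0 = 0) {
  if (!is.numeric(samples) || length(samples) < 2L) {
    abort_ppgbp("`samples` must be a numeric vector of length >= 2",
                "ppgbp_invalid_parameter")
  }
  if (!all(is.finite(samples))) {
    abort_ppgbp("all samples must be finite", "ppgbp_invalid_parameter")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    abort_ppgbp("`sampling_rate` must be a single positive number",
                "ppgbp_invalid_parameter")
  }
  channel <- match.arg(channel, PPG_CHANNELS)
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         channel = channel,
         t0 = as.numeric(t0)),
    class = "ppg_trace"
  )
}

#' @export
print.ppg_trace <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf("<ppg_trace> channel %s: %d samples @ %g Hz (%.1f s), t0 = %g s\n",
              x$channel, length(x$samples), x$sampling_rate, dur, x$t0))
  cat(sprintf("  level: mean %.4g, range [%.4g, %.4g]\n",
              mean(x$samples), min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.ppg_trace <- function(x) length(x$samples)

# sample times in seconds (absolute, including t0)
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1L) / trace$sampling_rate
}

trace_duration <- function(trace) length(trace$samples) / trace$sampling_rate
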