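# Beat detection and per-window HR / mNPV extraction.
#
# Per cardiac cycle the waveform yields three features (AC = peak-to-trough
# amplitude, DC = mean level, T = peak interval); HR = 60/T and mNPV = AC/DC
# are averaged over the analysis window after outlier beats are removed
# (runs of maxima without an intervening trough, and extremely short or long
# peak intervals).

#' Detect candidate beats in a PPG trace
#'
#' Finds local maxima separated by at least `min_interval` seconds whose
#' prominence exceeds `prominence_frac` of the local amplitude range. The
#' detector is polarity-agnostic: it orients the trace so that pulses point
#' upward (the orientation with positive skewness about the mean) before
#' searching for peaks. Each accepted peak becomes one beat spanning
#' trough-to-trough around it; the first and last peaks, whose spans are cut
#' by the trace edge, are excluded. Per beat the peak interval T (time to the
#' next accepted peak), the amplitude AC, the mean level DC, and the number
#' of prominent intra-beat maxima (evidence of "maxima continued" artifacts)
#' are recorded.
#'
#' @param trace A [ppg_trace].
#' @param min_interval Minimum peak separation in seconds (default 0.33 s,
#'   a 180 bpm ceiling). Must be at least `2 / sampling_rate`.
#' @param prominence_frac Minimum peak prominence as a fraction of the local
#'   (+/- 2 s) amplitude range (default 0.3).
#'
#' @return A `beat_table` data.frame with one row per beat: `peak_index`,
#'   `peak_time` (s), `T` (s), `AC`, `DC` (a.u.), `span_start`, `span_end`
#'   (sample indices), `n_maxima`, `valid`, `rejection_reason`. A constant
#'   trace yields zero rows.
#' @export
#' @examples
#' tr <- generate_pulse_train(60, 0.02, 1, 30, seed = 1)
#' head(detect_beats(tr))
detect_beats <- function(trace, min_interval = 0.33, prominence_frac = 0.3) {
  stopifnot(inherits(trace, "ppg_trace"))
  fs <- trace$sampling_rate
  if (min_interval < 2 / fs) {
    abort_ppgbp("`min_interval` must be at least 2 / sampling_rate",
                "ppgbp_invalid_parameter")
  }
  x <- trace$samples
  n <- length(x)
  if (n < 10L || n / fs < 2 * min_interval) {
    abort_ppgbp("trace too short for beat detection",
                "ppgbp_insufficient_data")
  }

  if (max(x) == min(x)) {
    return(empty_beat_table(trace))
  }

  # polarity orientation: pulses are sharp and sparse, so the upward
  # orientation has positive skewness about the mean
  centred <- x - mean(x)
  y <- if (mean(centred^3) < 0) -x else x

  # candidate local maxima (strict rise, non-strict fall tolerates plateaus)
  i <- 2:(n - 1L)
  cand <- i[y[i] > y[i - 1L] & y[i] >= y[i + 1L]]
  if (length(cand) == 0L) {
    return(empty_beat_table(trace))
  }

  # topographic prominence relative to the rolling (+/- 2 s) amplitude
  # range: on each side walk until a sample higher than the peak (or the
  # window edge); the side's base is the minimum over that stretch, and the
  # prominence is the drop from the peak to the higher of the two bases
  half <- max(2L, round(2 * fs))
  keep_prom <- vapply(cand, function(k) {
    lo <- max(1L, k - half); hi <- min(n, k + half)
    rng <- max(y[lo:hi]) - min(y[lo:hi])
    if (rng == 0) return(FALSE)
    left <- y[lo:(k - 1L)]
    higher <- which(left > y[k])
    base_l <- min(left[if (length(higher)) (max(higher) + 1L):length(left) else
      seq_along(left)])
    right <- y[(k + 1L):hi]
    higher <- which(right > y[k])
    base_r <- min(right[seq_len(if (length(higher)) min(higher) - 1L else
      length(right))])
    prom <- y[k] - max(base_l, base_r)
    prom >= prominence_frac * rng
  }, logical(1))
  cand <- cand[keep_prom]
  if (length(cand) < 3L) {
    return(empty_beat_table(trace))
  }

  # enforce minimum separation, keeping the higher of clashing peaks
  min_sep <- round(min_interval * fs)
  ord <- cand[order(y[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (k in ord) {
    if (!length(kept) || all(abs(kept - k) >= min_sep)) kept <- c(kept, k)
  }
  peaks <- sort(kept)
  np <- length(peaks)
  if (np < 3L) {
    return(empty_beat_table(trace))
  }

  # trough between each pair of consecutive peaks (on the oriented signal)
  troughs <- vapply(seq_len(np - 1L), function(k) {
    seg <- peaks[k]:peaks[k + 1L]
    seg[which.min(y[seg])]
  }, integer(1))

  # beats: peaks 2..np-1 have both flanking troughs and a next peak
  idx <- 2:(np - 1L)
  span_start <- troughs[idx - 1L]
  span_end <- troughs[idx]
  T_s <- (peaks[idx + 1L] - peaks[idx]) / fs

  feats <- t(vapply(seq_along(idx), function(j) {
    beat_features(trace, span_start[j], span_end[j])
  }, numeric(2)))

  n_max <- vapply(seq_along(idx), function(j) {
    count_prominent_maxima(y[span_start[j]:span_end[j]])
  }, integer(1))

  out <- data.frame(
    peak_index = peaks[idx],
    peak_time = trace$t0 + (peaks[idx] - 1L) / fs,
    T = T_s,
    AC = feats[, 1L],
    DC = feats[, 2L],
    span_start = span_start,
    span_end = span_end,
    n_maxima = n_max,
    valid = TRUE,
    rejection_reason = "none",
    stringsAsFactors = FALSE)
  attr(out, "sampling_rate") <- fs
  attr(out, "channel") <- trace$channel
  class(out) <- c("beat_table", "data.frame")
  out
}

empty_beat_table <- function(trace) {
  out <- data.frame(peak_index = integer(0), peak_time = numeric(0),
                    T = numeric(0), AC = numeric(0), DC = numeric(0),
                    span_start = integer(0), span_end = integer(0),
                    n_maxima = integer(0), valid = logical(0),
                    rejection_reason = character(0),
                    stringsAsFactors = FALSE)
  attr(out, "sampling_rate") <- trace$sampling_rate
  attr(out, "channel") <- trace$channel
  class(out) <- c("beat_table", "data.frame")
  out
}

# number of local maxima within a beat span rising above half the span's
# amplitude range: >= 2 marks a double-peak / "maxima continued" beat
count_prominent_maxima <- function(seg) {
  m <- length(seg)
  if (m < 3L) return(0L)
  thr <- min(seg) + 0.5 * (max(seg) - min(seg))
  i <- 2:(m - 1L)
  sum(seg[i] > seg[i - 1L] & seg[i] >= seg[i + 1L] & seg[i] > thr)
}

#' Per-beat amplitude and level
#'
#' The AC component is the peak-to-trough amplitude (max minus min) and the
#' DC component the arithmetic mean of the samples within one beat span.
#'
#' @param trace A [ppg_trace].
#' @param from,to Sample indices delimiting the beat span (inclusive); at
#'   least 3 samples.
#' @return Named numeric vector `c(AC =, DC =)`.
#' @export
#' @examples
#' tr <- ppg_trace(2 + 0.5 * sin(2 * pi * (0:59) / 60), 60)
#' beat_features(tr, 1, 60)  # AC = 1, DC = 2
beat_features <- function(trace, from, to) {
  stopifnot(inherits(trace, "ppg_trace"))
  n <- length(trace$samples)
  if (from < 1L || to > n || to < from) {
    abort_ppgbp("beat span outside trace", "ppgbp_invalid_span")
  }
  if (to - from + 1L < 3L) {
    abort_ppgbp("beat span must contain at least 3 samples",
                "ppgbp_invalid_span")
  }
  seg <- trace$samples[from:to]
  c(AC = max(seg) - min(seg), DC = mean(seg))
}

#' Remove outlier beats
#'
#' Flags and drops beats according to the waveform-analysis outlier rules:
#' beats whose span contains two or more prominent maxima with no
#' intervening trough below the prominence threshold ("maxima continued"),
#' beats with extremely short or long peak intervals (outside
#' `[t_min, t_max]`), and beats whose interval falls outside
#' `median(T) * (1 +/- rel_tol)` of the surviving beats.
#'
#' @param beats A `beat_table` from [detect_beats()], time-ordered.
#' @param t_min,t_max Absolute peak-interval bounds in seconds (defaults
#'   0.33 and 1.5 s, i.e. 40-180 bpm).
#' @param rel_tol Relative tolerance around the median interval (default
#'   0.3).
#' @return The valid beats (a `beat_table`), with attributes `n_rejected`
#'   and `rejected` (the flagged rows, `rejection_reason` filled in).
#' @export
remove_outlier_beats <- function(beats, t_min = 0.33, t_max = 1.5,
                                 rel_tol = 0.3) {
  stopifnot(inherits(beats, "beat_table"))
  if (nrow(beats) == 0L) {
    attr(beats, "n_rejected") <- 0L
    return(beats)
  }
  reason <- rep("none", nrow(beats))
  reason[beats$n_maxima >= 2L] <- "consecutive_maxima"
  reason[reason == "none" & beats$T < t_min] <- "T_too_short"
  reason[reason == "none" & beats$T > t_max] <- "T_too_long"
  ok <- reason == "none"
  if (any(ok)) {
    med <- median(beats$T[ok])
    rel_short <- ok & beats$T < med * (1 - rel_tol)
    rel_long <- ok & beats$T > med * (1 + rel_tol)
    reason[rel_short] <- "T_too_short"
    reason[rel_long] <- "T_too_long"
    ok <- reason == "none"
  }
  beats$rejection_reason <- reason
  beats$valid <- ok
  rejected <- beats[!ok, , drop = FALSE]
  out <- beats[ok, , drop = FALSE]
  attr(out, "sampling_rate") <- attr(beats, "sampling_rate")
  attr(out, "channel") <- attr(beats, "channel")
  attr(out, "n_rejected") <- nrow(rejected)
  attr(out, "rejected") <- rejected
  class(out) <- c("beat_table", "data.frame")
  out
}

#' Average HR and mNPV over an analysis window
#'
#' Restricts to valid beats whose peak falls in `[t_start, t_end)` and
#' averages the per-beat quantities: HR is the mean of 60/T (bpm) and mNPV
#' the mean of AC/DC. The first two seconds after cuff start are
#' conventionally excluded (`t_start = 2`) because cuff pressurization
#' contaminates the waveform.
#'
#' @param beats A `beat_table` (ideally after [remove_outlier_beats()]).
#' @param t_start,t_end Half-open analysis window in seconds.
#' @param min_beats Minimum number of valid beats required (default 10).
#' @return A one-row data.frame `HR`, `mNPV`, `n_beats`, `n_rejected`,
#'   `channel`.
#' @export
window_features <- function(beats, t_start = -Inf, t_end = Inf,
                            min_beats = 10L) {
  stopifnot(inherits(beats, "beat_table"))
  if (t_start >= t_end) {
    abort_ppgbp("`t_start` must be < `t_end`", "ppgbp_invalid_parameter")
  }
  inwin <- beats$valid & beats$peak_time >= t_start & beats$peak_time < t_end
  sel <- beats[inwin, , drop = FALSE]
  rej <- attr(beats, "rejected")
  n_rej <- if (is.null(rej)) {
    sum(!beats$valid & beats$peak_time >= t_start & beats$peak_time < t_end)
  } else {
    sum(rej$peak_time >= t_start & rej$peak_time < t_end)
  }
  if (nrow(sel) < min_beats) {
    abort_ppgbp(
      sprintf("only %d valid beats in window [%g, %g), need >= %d",
              nrow(sel), t_start, t_end, min_beats),
      "ppgbp_insufficient_beats")
  }
  data.frame(HR = mean(60 / sel$T),
             mNPV = mean(sel$AC / sel$DC),
             n_beats = nrow(sel),
             n_rejected = n_rej,
             channel = attr(beats, "channel") %||% NA_character_,
             stringsAsFactors = FALSE)
}

#' Extract window features for a set of session traces
#'
#' Runs [detect_beats()], [remove_outlier_beats()] and [window_features()]
#' on every trace of a session. Trace names must follow the
#' `<participant>_<condition>_<channel>` convention used by
#' [generate_session()] and the trace files.
#'
#' @param traces Named list of [ppg_trace] objects.
#' @param t_start,t_end Analysis window (defaults: 2 s after cuff start to
#'   the end of the trace).
#' @param min_interval,prominence_frac Detector settings, see
#'   [detect_beats()].
#' @param t_min,t_max,rel_tol Outlier rules, see [remove_outlier_beats()].
#' @param min_beats Minimum beats per window.
#' @return A data.frame `participant`, `condition`, `channel`, `HR`,
#'   `mNPV`, `n_beats`, `n_rejected`.
#' @export
#' @examples
#' s <- generate_session(generator_config(n_participants = 2, seed = 3))
#' f <- extract_features(s$traces)
#' head(f)
extract_features <- function(traces, t_start = 2, t_end = Inf,
                             min_interval = 0.33, prominence_frac = 0.3,
                             t_min = 0.33, t_max = 1.5, rel_tol = 0.3,
                             min_beats = 10L) {
  stopifnot(is.list(traces), !is.null(names(traces)))
  rows <- lapply(names(traces), function(nm) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1L]]
    if (length(parts) != 3L) {
      abort_ppgbp(sprintf(
        "trace name '%s' is not <participant>_<condition>_<channel>", nm),
        "ppgbp_invalid_parameter")
    }
    beats <- detect_beats(traces[[nm]], min_interval, prominence_frac)
    beats <- remove_outlier_beats(beats, t_min, t_max, rel_tol)
    wf <- window_features(beats, t_start, t_end, min_beats)
    cbind(data.frame(participant = parts[1L], condition = parts[2L],
                     channel = parts[3L], stringsAsFactors = FALSE),
          wf[, c("HR", "mNPV", "n_beats", "n_rejected")])
  })
  do.call(rbind, rows)
}
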