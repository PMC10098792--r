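# Shared fixtures: small configurations and hand-built beat tables.

# tiny session config for fast tests
tiny_config <- function(n = 3, noise = 0, jitter = 0, seed = 1, ...) {
  generator_config(n_participants = n, noise_sd_lnBP = noise,
                   jitter_cv = jitter, seed = seed, ...)
}

# beat table built directly from peak intervals (seconds)
make_beat_table <- function(T, fs = 60, n_maxima = rep(1L, length(T))) {
  peaks <- cumsum(c(1, round(T * fs)))[seq_along(T)]
  out <- data.frame(
    peak_index = peaks,
    peak_time = (peaks - 1) / fs,
    T = T,
    AC = rep(0.02, length(T)),
    DC = rep(1.0, length(T)),
    span_start = peaks - 10L,
    span_end = peaks + 10L,
    n_maxima = n_maxima,
    valid = TRUE,
    rejection_reason = "none",
    stringsAsFactors = FALSE)
  attr(out, "sampling_rate") <- fs
  attr(out, "channel") <- "NIR"
  class(out) <- c("beat_table", "data.frame")
  out
}

# truth features + cuff for a hand-set single-channel session
hand_session <- function(hr, mnpv, bp) {
  conds <- c("BL1", "BL2", "MA1", "MA2")
  list(
    features = data.frame(participant = "P01", condition = conds,
                          channel = "NIR", HR = hr, mNPV = mnpv,
                          stringsAsFactors = FALSE),
    cuff = data.frame(participant = "P01", condition = conds,
                      SBP = bp$SBP, DBP = bp$DBP, MAP = bp$MAP,
                      stringsAsFactors = FALSE))
}
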