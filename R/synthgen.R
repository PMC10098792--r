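# Synthetic multiwavelength PPG session generator.
#
# The generator emulates the measurement design of a 14-participant
# rest/mental-stress protocol: four LED wavelength channels recorded
# simultaneously at 60 Hz, four cuff readings per participant (BL1, BL2 at
# rest; MA1, MA2 under mental arithmetic), and cuff blood pressure produced
# by the same log-linear HR/mNPV model the estimator fits, so that every
# downstream stage can be checked against known ground truth.

# ---- beat template ---------------------------------------------------------
# One cardiac cycle as a function of phase in [0, 1): a dominant systolic
# upstroke plus a smaller, broader diastolic wave, so each beat has a single
# dominant maximum and a well-defined peak-to-trough amplitude.
beat_template_raw <- function(phi) {
  exp(-(phi - 0.30)^2 / (2 * 0.08^2)) +
    0.35 * exp(-(phi - 0.65)^2 / (2 * 0.12^2))
}

# Normalisation constants on a fine phase grid; the normalised template has
# range exactly 1, so a beat with amplitude A has peak-to-trough AC = A (up
# to sampling of the peak) and the amplitude offset is removed through the
# template's mean so that the per-beat mean stays at the requested DC.
.template_const <- local({
  phi <- seq(0, 1, length.out = 4096L)[-4096L]
  g <- beat_template_raw(phi)
  list(min = min(g), max = max(g), mean_norm = mean((g - min(g)) / (max(g) - min(g))))
})

beat_template <- function(phi) {
  (beat_template_raw(phi) - .template_const$min) /
    (.template_const$max - .template_const$min)
}

# Secondary narrow bump used for the double-peak ("maxima continued")
# artifact: a second local maximum of comparable height within the beat.
double_peak_bump <- function(phi) {
  0.9 * exp(-(phi - 0.55)^2 / (2 * 0.03^2))
}

# ---- pulse train -----------------------------------------------------------

#' Generate a synthetic PPG pulse train
#'
#' Emits one channel's uniformly sampled pulse waveform with a requested
#' heart rate, AC/DC ratio (mNPV) and mean level (DC). Beat periods are
#' `60 / hr` seconds with optional multiplicative log-normal jitter of
#' coefficient of variation `jitter_cv`; beat-level artifacts (a second
#' intra-beat maximum, or a missed beat) can be injected at given rates, and
#' an optional decaying transient at the window start mimics the motion
#' artifact caused by cuff pressurization.
#'
#' @param hr Heart rate in bpm, in (30, 220).
#' @param mnpv Target AC/DC ratio of the waveform, in (0, 0.5).
#' @param dc Target mean level in arbitrary units, > 0.
#' @param duration Trace duration in seconds; must cover at least two beats.
#' @param fs Sampling rate in Hz (default 60).
#' @param jitter_cv Coefficient of variation of the multiplicative
#'   beat-period jitter (0 = perfectly periodic).
#' @param seed Optional integer; when given, the trace is generated under a
#'   local seed and is bit-identical across calls.
#' @param channel Channel label for the returned trace.
#' @param double_peak_prob,missed_beat_prob Per-beat artifact probabilities.
#' @param onset_artifact If `TRUE`, adds a decaying cuff-pressurization
#'   transient over roughly the first two seconds.
#' @param t0 Time offset of the first sample (s).
#'
#' @return A [ppg_trace].
#' @export
#' @examples
#' tr <- generate_pulse_train(hr = 60, mnpv = 0.02, dc = 1, duration = 30,
#'                            seed = 1)
#' tr
generate_pulse_train <- function(hr, mnpv, dc, duration, fs = 60,
                                 jitter_cv = 0, seed = NULL,
                                 channel = "NIR",
                                 double_peak_prob = 0, missed_beat_prob = 0,
                                 onset_artifact = FALSE, t0 = 0) {
  if (!is.numeric(hr) || length(hr) != 1L || hr <= 30 || hr >= 220) {
    abort_ppgbp("`hr` must be a single value in (30, 220) bpm",
                "ppgbp_invalid_parameter")
  }
  if (!is.numeric(mnpv) || length(mnpv) != 1L || mnpv <= 0 || mnpv >= 0.5) {
    abort_ppgbp("`mnpv` must be a single value in (0, 0.5)",
                "ppgbp_invalid_parameter")
  }
  if (!is.numeric(dc) || length(dc) != 1L || dc <= 0) {
    abort_ppgbp("`dc` must be a single positive value",
                "ppgbp_invalid_parameter")
  }
  if (jitter_cv < 0 || double_peak_prob < 0 || double_peak_prob > 1 ||
      missed_beat_prob < 0 || missed_beat_prob > 1) {
    abort_ppgbp("jitter_cv must be >= 0 and artifact probabilities in [0, 1]",
                "ppgbp_invalid_parameter")
  }
  period <- 60 / hr
  if (duration < 2 * period) {
    abort_ppgbp(
      sprintf("duration (%.3g s) must cover at least two beats (period %.3g s)",
              duration, period),
      "ppgbp_insufficient_duration")
  }

  build <- function() {
    # beat onsets: cumulative jittered periods covering [0, duration]
    if (jitter_cv > 0) {
      sdlog <- sqrt(log(1 + jitter_cv^2))
      draw_period <- function() period * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    } else {
      draw_period <- function() period
    }
    starts <- 0
    periods <- numeric(0)
    dbl <- logical(0)
    miss <- logical(0)
    while (starts[length(starts)] <= duration) {
      periods <- c(periods, draw_period())
      dbl <- c(dbl, runif(1) < double_peak_prob)
      miss <- c(miss, runif(1) < missed_beat_prob)
      starts <- c(starts, starts[length(starts)] + periods[length(periods)])
    }
    starts <- starts[-length(starts)]

    n <- floor(duration * fs)
    t <- (seq_len(n) - 1L) / fs
    j <- findInterval(t, starts)
    phi <- (t - starts[j]) / periods[j]
    amp <- mnpv * dc
    beat_amp <- ifelse(miss[j], 0, amp)
    x <- dc + beat_amp * (beat_template(phi) - .template_const$mean_norm)
    x <- x + ifelse(dbl[j], beat_amp * double_peak_bump(phi), 0)
    if (onset_artifact) {
      x <- x + 4 * amp * exp(-t / 0.6)
    }
    ppg_trace(x, fs, channel, t0 = t0)
  }

  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# ---- generator configuration ----------------------------------------------

#' Default per-wavelength mNPV parameters
#'
#' Resting mNPV levels and dispersions per LED channel match group statistics
#' from a published four-wavelength finger-PPG study of 14 young adults.
#' Stress levels default to the resting level times a shared vasoconstriction
#' ratio of 0.529 (the observed rest-to-stress mNPV ratio, nearly identical
#' across the four wavelengths): the rest-to-stress tone change is a single
#' systemic process that every wavelength observes at its own level, which
#' keeps log mNPV changes consistent across channels.
#'
#' @return A data.frame with one row per channel and columns
#'   `channel`, `mnpv_rest_mean`, `mnpv_rest_sd`, `mnpv_stress_mean`,
#'   `mnpv_stress_sd`.
#' @export
default_wavelength_params <- function() {
  rest_mean <- c(B = 0.0378, G = 0.0364, R = 0.0206, NIR = 0.0247)
  data.frame(
    channel = PPG_CHANNELS,
    mnpv_rest_mean = unname(rest_mean),
    mnpv_rest_sd = c(0.0179, 0.0208, 0.0104, 0.0115),
    mnpv_stress_mean = unname(rest_mean) * 0.529,
    mnpv_stress_sd = c(0.0074, 0.0086, 0.0041, 0.0047),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic session generator
#'
#' Defaults reproduce the study conditions the generator emulates: 14
#' participants, 60 Hz sampling, 28 s analysis windows, resting HR
#' 72.8 +/- 12.7 bpm rising to 89.8 +/- 15.8 bpm under mental arithmetic,
#' per-wavelength mNPV levels from [default_wavelength_params()], baseline
#' cuff pressure 112.3/68.5 mmHg (SD 12.3/6.3), and log-linear BP model
#' coefficients taken from the per-BP-type optimal wavelengths (near-infrared
#' for SBP; blue for DBP and MAP).
#'
#' @param n_participants Number of simulated participants (>= 2).
#' @param sampling_rate PPG sampling rate, Hz.
#' @param window_duration Duration of each emitted trace, seconds.
#' @param wavelength_params Data frame as returned by
#'   [default_wavelength_params()].
#' @param hr_rest_mean,hr_rest_sd,hr_stress_mean,hr_stress_sd Heart-rate
#'   distribution per condition phase, bpm.
#' @param model_coefficients Named list with elements `SBP`, `DBP`, `MAP`,
#'   each a named vector `c(a=, b=, c=)`: coefficients of
#'   \eqn{\Delta\ln BP = a \Delta\ln HR + b \Delta\ln mNPV + c}.
#' @param bp_baseline Named list `SBP_mean`, `SBP_sd`, `DBP_mean`, `DBP_sd`
#'   for the BL1 reference cuff reading, mmHg.
#' @param noise_sd_lnBP SD of the Gaussian noise added to each condition's
#'   log BP (dimensionless; 0 gives an exactly recoverable model).
#' @param artifact_rates Named list `double_peak_prob`, `missed_beat_prob`.
#' @param jitter_cv Beat-period jitter coefficient of variation.
#' @param within_frac Fraction of each condition draw's variance attributed
#'   to measurement-to-measurement (BL1 vs BL2) fluctuation rather than the
#'   stable participant level, in [0, 1].
#' @param dc_mean,dc_cv Mean and coefficient of variation of the per
#'   participant-channel DC level (arbitrary units).
#' @param onset_artifact Add a cuff-pressurization transient at trace start.
#' @param seed Integer seed; the whole session is generated under it.
#'
#' @return An object of class `generator_config` (a validated list).
#' @export
#' @examples
#' cfg <- generator_config(n_participants = 3, seed = 42)
#' names(cfg)
generator_config <- function(n_participants = 14,
                             sampling_rate = 60,
                             window_duration = 28,
                             wavelength_params = default_wavelength_params(),
                             hr_rest_mean = 72.8, hr_rest_sd = 12.7,
                             hr_stress_mean = 89.8, hr_stress_sd = 15.8,
                             model_coefficients = list(
                               SBP = c(a = 0.373, b = -0.012, c = 0.001),
                               DBP = c(a = 0.203, b = -0.117, c = 0.024),
                               MAP = c(a = 0.245, b = -0.084, c = 0.011)),
                             bp_baseline = list(SBP_mean = 112.3, SBP_sd = 12.3,
                                                DBP_mean = 68.5, DBP_sd = 6.3),
                             noise_sd_lnBP = 0.05,
                             artifact_rates = list(double_peak_prob = 0,
                                                   missed_beat_prob = 0),
                             jitter_cv = 0.04,
                             within_frac = 0.3,
                             dc_mean = 1.0, dc_cv = 0.1,
                             onset_artifact = FALSE,
                             seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              sampling_rate = sampling_rate,
              window_duration = window_duration,
              wavelength_params = wavelength_params,
              hr_rest_mean = hr_rest_mean, hr_rest_sd = hr_rest_sd,
              hr_stress_mean = hr_stress_mean, hr_stress_sd = hr_stress_sd,
              model_coefficients = model_coefficients,
              bp_baseline = bp_baseline,
              noise_sd_lnBP = noise_sd_lnBP,
              artifact_rates = artifact_rates,
              jitter_cv = jitter_cv,
              within_frac = within_frac,
              dc_mean = dc_mean, dc_cv = dc_cv,
              onset_artifact = isTRUE(onset_artifact),
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  wp <- cfg$wavelength_params
  need <- c("channel", "mnpv_rest_mean", "mnpv_rest_sd",
            "mnpv_stress_mean", "mnpv_stress_sd")
  if (!is.data.frame(wp) || !all(need %in% names(wp)) ||
      !setequal(wp$channel, PPG_CHANNELS)) {
    abort_ppgbp("`wavelength_params` must have one row per channel B/G/R/NIR",
                "ppgbp_invalid_parameter")
  }
  pos <- c(unlist(wp[setdiff(need, "channel")]),
           cfg$hr_rest_mean, cfg$hr_rest_sd, cfg$hr_stress_mean,
           cfg$hr_stress_sd,
           unlist(cfg$bp_baseline), cfg$sampling_rate, cfg$window_duration,
           cfg$dc_mean)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    abort_ppgbp("all means, SDs, rates and durations must be strictly positive",
                "ppgbp_invalid_parameter")
  }
  probs <- c(cfg$artifact_rates$double_peak_prob,
             cfg$artifact_rates$missed_beat_prob, cfg$within_frac)
  if (any(probs < 0) || any(probs > 1)) {
    abort_ppgbp("probabilities must lie in [0, 1]", "ppgbp_invalid_parameter")
  }
  if (cfg$noise_sd_lnBP < 0 || cfg$jitter_cv < 0 || cfg$dc_cv < 0) {
    abort_ppgbp("noise_sd_lnBP, jitter_cv and dc_cv must be >= 0",
                "ppgbp_invalid_parameter")
  }
  if (!setequal(names(cfg$model_coefficients), BP_TYPES) ||
      !all(vapply(cfg$model_coefficients,
                  function(v) all(c("a", "b", "c") %in% names(v)), logical(1)))) {
    abort_ppgbp("`model_coefficients` needs SBP/DBP/MAP entries with a, b, c",
                "ppgbp_invalid_parameter")
  }
  # Nyquist guard: the sampling rate must comfortably exceed twice the
  # fastest plausible heart frequency (mean + 4 SD).
  max_hf <- (cfg$hr_stress_mean + 4 * cfg$hr_stress_sd) / 60
  if (cfg$sampling_rate <= 2 * max_hf) {
    abort_ppgbp("sampling_rate must exceed twice the maximum heart frequency",
                "ppgbp_invalid_parameter")
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> %d participants, %g Hz, %g s windows, seed %d\n",
    x$n_participants, x$sampling_rate, x$window_duration, x$seed))
  cat(sprintf("  HR rest %.1f+/-%.1f, stress %.1f+/-%.1f bpm; lnBP noise SD %g\n",
              x$hr_rest_mean, x$hr_rest_sd, x$hr_stress_mean, x$hr_stress_sd,
              x$noise_sd_lnBP))
  invisible(x)
}

# moment-matched log-normal sdlog for mean m and sd s
lnorm_sdlog <- function(m, s) sqrt(log(1 + (s / m)^2))

# ---- session generation ----------------------------------------------------

#' Generate one synthetic study session
#'
#' Simulates `n_participants` participants through the four-measurement
#' protocol (BL1, BL2 at rest; MA1, MA2 under stress). For each participant
#' it draws a cardiac truth (one HR per condition, shared by all channels)
#' and a vascular-tone truth (one log-scale deviate per condition driving
#' mNPV in every channel at its own wavelength-specific level), sets the
#' BL1 cuff reading from the baseline distribution, and produces the other
#' conditions' cuff BP through the log-linear model
#' \eqn{\ln BP_{cond} = \ln BP_{BL1} + a\,\Delta\ln HR + b\,\Delta\ln mNPV
#' + c + \epsilon}, \eqn{\epsilon \sim N(0, \sigma_{\ln BP})}. Optionally
#' emits the 16 pulse-train traces per participant (4 channels x 4
#' conditions).
#'
#' @param config A [generator_config()].
#' @param make_traces If `FALSE`, skip waveform synthesis and return only
#'   cuff readings and ground truth (fast; useful for model-level studies).
#'
#' @return An object of class `ppg_session`: a list with elements
#'   \describe{
#'     \item{traces}{named list of [ppg_trace] objects
#'       (`"P01_BL1_B"`, ...), or `NULL`,}
#'     \item{cuff}{data.frame `participant`, `condition`, `SBP`, `DBP`,
#'       `MAP` (mmHg),}
#'     \item{truth}{list with `features` (per participant x condition x
#'       channel: `HR`, `mNPV`, `DC`) and `bp` (the noise-bearing cuff
#'       values, identical to `cuff`).}
#'   }
#' @export
#' @examples
#' s <- generate_session(generator_config(n_participants = 3, seed = 7),
#'                       make_traces = FALSE)
#' head(s$cuff)
generate_session <- function(config, make_traces = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_participants < 2L) {
    abort_ppgbp("n_participants must be >= 2", "ppgbp_invalid_parameter")
  }
  withr::with_seed(config$seed, generate_session_impl(config, make_traces))
}

generate_session_impl <- function(config, make_traces) {
  wp <- config$wavelength_params
  wp <- wp[match(PPG_CHANNELS, wp$channel), ]
  wf <- config$within_frac
  phase_of <- c(BL1 = "rest", BL2 = "rest", MA1 = "stress", MA2 = "stress")

  # shared log-scale tone dispersion per phase (pooled across channels)
  sigma_ln <- c(
    rest = mean(lnorm_sdlog(wp$mnpv_rest_mean, wp$mnpv_rest_sd)),
    stress = mean(lnorm_sdlog(wp$mnpv_stress_mean, wp$mnpv_stress_sd)))
  level <- list(
    rest = setNames(wp$mnpv_rest_mean, wp$channel),
    stress = setNames(wp$mnpv_stress_mean, wp$channel))
  hr_mean <- c(rest = config$hr_rest_mean, stress = config$hr_stress_mean)
  hr_sd <- c(rest = config$hr_rest_sd, stress = config$hr_stress_sd)

  ids <- sprintf("P%02d", seq_len(config$n_participants))
  feat_list <- vector("list", length(ids))
  cuff_list <- vector("list", length(ids))
  traces <- if (make_traces) list() else NULL

  for (p in seq_along(ids)) {
    # participant-level deviates per phase
    z_hr <- c(rest = rnorm(1), stress = rnorm(1))
    u_tone <- c(rest = rnorm(1), stress = rnorm(1))

    hr <- numeric(4); names(hr) <- PPG_CONDITIONS
    w <- numeric(4); names(w) <- PPG_CONDITIONS
    for (cond in PPG_CONDITIONS) {
      ph <- phase_of[[cond]]
      repeat {
        val <- hr_mean[[ph]] + hr_sd[[ph]] *
          (sqrt(1 - wf) * z_hr[[ph]] + sqrt(wf) * rnorm(1))
        if (val > 40 && val < 200) break
      }
      hr[cond] <- val
      w[cond] <- sqrt(1 - wf) * u_tone[[ph]] + sqrt(wf) * rnorm(1)
    }

    mnpv <- matrix(NA_real_, 4, 4, dimnames = list(PPG_CONDITIONS, PPG_CHANNELS))
    for (cond in PPG_CONDITIONS) {
      ph <- phase_of[[cond]]
      s <- sigma_ln[[ph]]
      mnpv[cond, ] <- exp(log(level[[ph]]) - s^2 / 2 + s * w[cond])
    }

    dc <- setNames(config$dc_mean * exp(rnorm(4, 0, config$dc_cv) -
                                          config$dc_cv^2 / 2), PPG_CHANNELS)

    # BL1 reference cuff reading
    bb <- config$bp_baseline
    repeat {
      sbp1 <- rnorm(1, bb$SBP_mean, bb$SBP_sd)
      dbp1 <- rnorm(1, bb$DBP_mean, bb$DBP_sd)
      if (sbp1 > dbp1 + 15 && dbp1 > 30) break
    }
    bl1 <- c(SBP = sbp1, DBP = dbp1, MAP = map_one_third(sbp1, dbp1))

    dln_hr <- log(hr / hr["BL1"])
    # systemic log-tone change: channel mean of per-channel log changes
    dln_mnpv <- rowMeans(log(mnpv) - matrix(log(mnpv["BL1", ]), 4, 4,
                                            byrow = TRUE))

    bp <- matrix(NA_real_, 4, 3, dimnames = list(PPG_CONDITIONS, BP_TYPES))
    bp["BL1", ] <- bl1
    for (cond in c("BL2", "MA1", "MA2")) {
      for (tries in 1:100) {
        vals <- vapply(BP_TYPES, function(bt) {
          cf <- config$model_coefficients[[bt]]
          eps <- if (config$noise_sd_lnBP > 0) {
            rnorm(1, 0, config$noise_sd_lnBP)
          } else 0
          bl1[[bt]] * exp(cf[["a"]] * dln_hr[[cond]] +
                            cf[["b"]] * dln_mnpv[[cond]] + cf[["c"]] + eps)
        }, numeric(1))
        if (vals[["SBP"]] > vals[["DBP"]]) break
      }
      bp[cond, ] <- vals
    }

    feat_list[[p]] <- data.frame(
      participant = ids[p],
      condition = rep(PPG_CONDITIONS, each = 4L),
      channel = rep(PPG_CHANNELS, times = 4L),
      HR = rep(unname(hr), each = 4L),
      mNPV = as.vector(t(mnpv)),
      DC = rep(unname(dc), times = 4L),
      stringsAsFactors = FALSE)
    cuff_list[[p]] <- data.frame(
      participant = ids[p], condition = PPG_CONDITIONS,
      SBP = bp[, "SBP"], DBP = bp[, "DBP"], MAP = bp[, "MAP"],
      row.names = NULL, stringsAsFactors = FALSE)

    if (make_traces) {
      for (cond in PPG_CONDITIONS) {
        for (ch in PPG_CHANNELS) {
          nm <- paste(ids[p], cond, ch, sep = "_")
          traces[[nm]] <- generate_pulse_train(
            hr = hr[[cond]], mnpv = mnpv[cond, ch], dc = dc[[ch]],
            duration = config$window_duration, fs = config$sampling_rate,
            jitter_cv = config$jitter_cv, channel = ch,
            double_peak_prob = config$artifact_rates$double_peak_prob,
            missed_beat_prob = config$artifact_rates$missed_beat_prob,
            onset_artifact = config$onset_artifact)
        }
      }
    }
  }

  cuff <- do.call(rbind, cuff_list)
  out <- list(traces = traces,
              cuff = cuff,
              truth = list(features = do.call(rbind, feat_list),
                           bp = cuff),
              config = config)
  class(out) <- "ppg_session"
  out
}

#' @export
print.ppg_session <- function(x, ...) {
  np <- length(unique(x$cuff$participant))
  cat(sprintf("<ppg_session> %d participants, %d cuff readings, %s traces\n",
              np, nrow(x$cuff),
              if (is.null(x$traces)) "no" else length(x$traces)))
  invisible(x)
}
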