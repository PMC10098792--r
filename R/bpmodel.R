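# Baseline-referenced log-linear blood pressure model.
#
# All quantities enter as natural-log differences against the BL1 reference
# measurement (delta-ln transform), which normalises the distributions and
# suppresses between-participant level differences. Per BP type and
# wavelength, delta-ln BP is regressed on delta-ln HR and delta-ln mNPV by
# ordinary least squares; estimates in mmHg are recovered by multiplying
# the BL1 cuff value by exp(predicted delta-ln BP).

#' Natural-log difference against a reference
#'
#' `delta_ln(v, r)` is `ln(v / r) = ln v - ln r`, the baseline-referenced
#' log change used for every model quantity.
#'
#' @param value,reference Positive quantities (vectorised).
#' @return `log(value / reference)`.
#' @export
#' @examples
#' delta_ln(121.6, 112.3)
delta_ln <- function(value, reference) {
  if (any(value <= 0) || any(reference <= 0)) {
    abort_ppgbp("delta_ln requires strictly positive inputs",
                "ppgbp_invalid_parameter")
  }
  log(value) - log(reference)
}

#' Mean arterial pressure by the one-third rule
#'
#' `MAP = DBP + (SBP - DBP) / 3`: diastole occupies roughly two-thirds of
#' the cardiac cycle at rest, so MAP sits one third of the pulse pressure
#' above DBP.
#'
#' @param sbp,dbp Systolic and diastolic pressure in mmHg (vectorised);
#'   `sbp > dbp > 0` elementwise.
#' @return MAP in mmHg.
#' @export
#' @examples
#' map_one_third(112.3, 68.5)  # 83.1
map_one_third <- function(sbp, dbp) {
  if (any(dbp <= 0) || any(sbp <= dbp)) {
    abort_ppgbp("need sbp > dbp > 0", "ppgbp_invalid_pressures")
  }
  dbp + (sbp - dbp) / 3
}

#' Build the delta-ln analysis table
#'
#' For every participant and channel, emits one row per non-reference
#' condition (BL2, MA1, MA2) holding the five log changes against BL1:
#' `dln_HR`, `dln_mNPV` (from the window features) and `dln_SBP`,
#' `dln_DBP`, `dln_MAP` (from the cuff readings).
#'
#' @param features Data.frame `participant`, `condition`, `channel`, `HR`,
#'   `mNPV` (e.g. from [extract_features()] or generator truth).
#' @param cuff Data.frame `participant`, `condition`, `SBP`, `DBP`, `MAP`.
#' @return A data.frame with columns `participant`, `condition`, `channel`,
#'   `dln_HR`, `dln_mNPV`, `dln_SBP`, `dln_DBP`, `dln_MAP`.
#' @export
#' @examples
#' s <- generate_session(generator_config(n_participants = 3, seed = 1),
#'                       make_traces = FALSE)
#' d <- build_delta_table(s$truth$features, s$cuff)
#' nrow(d)  # 3 participants x 4 channels x 3 conditions
build_delta_table <- function(features, cuff) {
  need_f <- c("participant", "condition", "channel", "HR", "mNPV")
  need_c <- c("participant", "condition", "SBP", "DBP", "MAP")
  if (!all(need_f %in% names(features))) {
    abort_ppgbp("`features` must have participant/condition/channel/HR/mNPV",
                "ppgbp_schema_error")
  }
  if (!all(need_c %in% names(cuff))) {
    abort_ppgbp("`cuff` must have participant/condition/SBP/DBP/MAP",
                "ppgbp_schema_error")
  }
  rows <- list()
  for (p in unique(features$participant)) {
    cp <- cuff[cuff$participant == p, , drop = FALSE]
    ref_bp <- cp[cp$condition == "BL1", , drop = FALSE]
    if (nrow(ref_bp) != 1L) {
      abort_ppgbp(sprintf("participant %s has no BL1 cuff reading", p),
                  "ppgbp_missing_reference")
    }
    fp <- features[features$participant == p, , drop = FALSE]
    for (ch in unique(fp$channel)) {
      fc <- fp[fp$channel == ch, , drop = FALSE]
      ref_f <- fc[fc$condition == "BL1", , drop = FALSE]
      if (nrow(ref_f) != 1L) {
        abort_ppgbp(sprintf(
          "participant %s channel %s has no BL1 window features", p, ch),
          "ppgbp_missing_reference")
      }
      for (cond in c("BL2", "MA1", "MA2")) {
        f1 <- fc[fc$condition == cond, , drop = FALSE]
        c1 <- cp[cp$condition == cond, , drop = FALSE]
        if (nrow(f1) != 1L || nrow(c1) != 1L) {
          warning(sprintf("participant %s channel %s: condition %s missing, row omitted",
                          p, ch, cond), call. = FALSE)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          participant = p, condition = cond, channel = ch,
          dln_HR = delta_ln(f1$HR, ref_f$HR),
          dln_mNPV = delta_ln(f1$mNPV, ref_f$mNPV),
          dln_SBP = delta_ln(c1$SBP, ref_bp$SBP),
          dln_DBP = delta_ln(c1$DBP, ref_bp$DBP),
          dln_MAP = delta_ln(c1$MAP, ref_bp$MAP),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    abort_ppgbp("no delta rows could be built", "ppgbp_missing_reference")
  }
  do.call(rbind, rows)
}

#' Fit the log-linear BP model for one BP type and wavelength
#'
#' Ordinary least squares of the chosen delta-ln BP on delta-ln HR,
#' delta-ln mNPV and an intercept, solved by the normal equations on the
#' 3-column design with an explicit rank check. Reports coefficients
#' (`a` on HR, `b` on mNPV, intercept `c`), standardized betas
#' (`coef * SD(x) / SD(y)`), two-sided per-coefficient t-test p-values with
#' `n - 3` degrees of freedom, the coefficient of determination and the
#' overall F-test p-value.
#'
#' @param delta Delta table from [build_delta_table()].
#' @param bp_type One of `"SBP"`, `"DBP"`, `"MAP"`.
#' @param channel One of `"B"`, `"G"`, `"R"`, `"NIR"`.
#' @return An object of class `bp_fit`.
#' @export
fit_bp_model <- function(delta, bp_type, channel) {
  bp_type <- match.arg(bp_type, BP_TYPES)
  channel <- match.arg(channel, PPG_CHANNELS)
  d <- delta[delta$channel == channel, , drop = FALSE]
  n <- nrow(d)
  if (n < 4L) {
    abort_ppgbp("need at least 4 rows to fit the 3-parameter model",
                "ppgbp_insufficient_data")
  }
  y <- d[[paste0("dln_", bp_type)]]
  if (sd(y) == 0) {
    abort_ppgbp("zero-variance response: R^2 undefined",
                "ppgbp_degenerate_input")
  }
  X <- cbind(intercept = 1, dln_HR = d$dln_HR, dln_mNPV = d$dln_mNPV)
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12) {
    abort_ppgbp("rank-deficient design (constant or collinear predictors)",
                "ppgbp_singular_design")
  }
  beta <- drop(solve(XtX, crossprod(X, y)))
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  df <- n - 3L
  sigma2 <- ss_res / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  f <- ((ss_tot - ss_res) / 2) / sigma2
  overall_p <- pf(f, 2, df, lower.tail = FALSE)
  out <- list(
    bp_type = bp_type, channel = channel,
    a = unname(beta["dln_HR"]), b = unname(beta["dln_mNPV"]),
    c = unname(beta["intercept"]),
    std_beta_a = unname(beta["dln_HR"] * sd(d$dln_HR) / sd(y)),
    std_beta_b = unname(beta["dln_mNPV"] * sd(d$dln_mNPV) / sd(y)),
    p_a = unname(pval["dln_HR"]), p_b = unname(pval["dln_mNPV"]),
    p_c = unname(pval["intercept"]),
    R2 = r2, F = f, overall_p = overall_p, n = n, df = df,
    sigma = sqrt(sigma2), residuals = resid, fitted = fitted)
  class(out) <- "bp_fit"
  out
}

#' @export
print.bp_fit <- function(x, ...) {
  cat(sprintf("<bp_fit> dln %s ~ dln HR + dln mNPV, channel %s (n = %d)\n",
              x$bp_type, x$channel, x$n))
  cat(sprintf("  a = %.4f (std b %.3f, p %.3g)  b = %.4f (std b %.3f, p %.3g)  c = %.4f (p %.3g)\n",
              x$a, x$std_beta_a, x$p_a, x$b, x$std_beta_b, x$p_b, x$c, x$p_c))
  cat(sprintf("  R^2 = %.3f, overall p = %.3g\n", x$R2, x$overall_p))
  invisible(x)
}

#' Fit all 12 BP-type x wavelength models
#'
#' @param delta Delta table from [build_delta_table()].
#' @param channels Channels to fit (default all present in `delta`).
#' @return An object of class `bp_fit_set`: a named list of [fit_bp_model()]
#'   results keyed `"<bp_type>.<channel>"`.
#' @export
fit_all_models <- function(delta, channels = NULL) {
  channels <- channels %||% intersect(PPG_CHANNELS, unique(delta$channel))
  fits <- list()
  for (bt in BP_TYPES) {
    for (ch in channels) {
      fits[[paste(bt, ch, sep = ".")]] <- fit_bp_model(delta, bt, ch)
    }
  }
  class(fits) <- "bp_fit_set"
  fits
}

#' @export
print.bp_fit_set <- function(x, ...) {
  cat(sprintf("<bp_fit_set> %d fits\n", length(x)))
  print(r2_matrix(x))
  invisible(x)
}

#' Matrix of coefficients of determination
#'
#' Arranges the R-squared of each fit into the 3 x 4 (BP type x wavelength)
#' matrix used for the wavelength comparison.
#'
#' @param fits A `bp_fit_set` from [fit_all_models()].
#' @return A numeric matrix of class `r2_matrix`, rows SBP/DBP/MAP, columns
#'   B/G/R/NIR (columns restricted to fitted channels).
#' @export
r2_matrix <- function(fits) {
  stopifnot(inherits(fits, "bp_fit_set"))
  chs <- unique(vapply(fits, function(f) f$channel, character(1)))
  chs <- PPG_CHANNELS[PPG_CHANNELS %in% chs]
  m <- matrix(NA_real_, length(BP_TYPES), length(chs),
              dimnames = list(BP_TYPES, chs))
  for (f in fits) m[f$bp_type, f$channel] <- f$R2
  class(m) <- c("r2_matrix", "matrix", "array")
  m
}

#' @export
print.r2_matrix <- function(x, ...) {
  print(round(unclass(x), 3))
  invisible(x)
}

#' Estimate blood pressure from window features
#'
#' For each delta row, the predicted log change is
#' `a * dln_HR + b * dln_mNPV + c` and the BP estimate is the participant's
#' BL1 cuff value times its exponential.
#'
#' @param delta Delta table from [build_delta_table()].
#' @param cuff Cuff table (must contain each participant's BL1 row).
#' @param fits A single `bp_fit` or a `bp_fit_set`.
#' @return A data.frame `participant`, `condition`, `channel`, `bp_type`,
#'   `estimated`, `measured` (mmHg).
#' @export
estimate_bp <- function(delta, cuff, fits) {
  if (inherits(fits, "bp_fit")) fits <- structure(list(fits),
                                                  class = "bp_fit_set")
  stopifnot(inherits(fits, "bp_fit_set"))
  bl1 <- cuff[cuff$condition == "BL1", , drop = FALSE]
  out <- list()
  for (f in fits) {
    d <- delta[delta$channel == f$channel, , drop = FALSE]
    ref <- bl1[match(d$participant, bl1$participant), f$bp_type]
    if (any(is.na(ref))) {
      abort_ppgbp("missing BL1 cuff reading for some participants",
                  "ppgbp_missing_reference")
    }
    pred <- f$a * d$dln_HR + f$b * d$dln_mNPV + f$c
    meas_all <- cuff[[f$bp_type]][match(paste(d$participant, d$condition),
                                        paste(cuff$participant, cuff$condition))]
    out[[length(out) + 1L]] <- data.frame(
      participant = d$participant, condition = d$condition,
      channel = f$channel, bp_type = f$bp_type,
      estimated = ref * exp(pred),
      measured = meas_all,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
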