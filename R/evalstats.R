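# Evaluation layer: wavelength comparison of estimation accuracy and
# agreement statistics against the cuff reference.

#' Published four-wavelength R-squared matrix
#'
#' Coefficients of determination from a published 14-participant validation
#' study of cuffless BP estimation at four LED wavelengths (one pooled
#' regression per BP type x wavelength, n = 42): a convenient worked-example
#' input for [mean_r2_by_channel()], [rm_anova_oneway()] and
#' [tukey_hsd_channels()].
#'
#' @return A 3 x 4 `r2_matrix` (rows SBP/DBP/MAP, columns B/G/R/NIR).
#' @export
#' @examples
#' mean_r2_by_channel(reference_r2_matrix())
reference_r2_matrix <- function() {
  m <- matrix(c(0.612, 0.549, 0.592, 0.634,
                0.497, 0.406, 0.480, 0.470,
                0.630, 0.541, 0.607, 0.598),
              nrow = 3, byrow = TRUE,
              dimnames = list(BP_TYPES, PPG_CHANNELS))
  class(m) <- c("r2_matrix", "matrix", "array")
  m
}

check_r2_matrix <- function(m) {
  if (!is.matrix(m) || any(!is.finite(m))) {
    abort_ppgbp("need a complete numeric BP-type x channel matrix",
                "ppgbp_incomplete_matrix")
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    abort_ppgbp("need at least 2 rows and 2 columns",
                "ppgbp_incomplete_matrix")
  }
  invisible(m)
}

#' Per-wavelength mean accuracy
#'
#' Averages the coefficient of determination over the BP types (rows) for
#' each wavelength (column); dispersion is the sample SD (n - 1
#' denominator).
#'
#' @param m An `r2_matrix` (BP types x channels), complete.
#' @return A data.frame `channel`, `mean`, `sd`.
#' @export
#' @examples
#' mean_r2_by_channel(reference_r2_matrix())
mean_r2_by_channel <- function(m) {
  check_r2_matrix(m)
  data.frame(channel = colnames(m),
             mean = unname(colMeans(m)),
             sd = unname(apply(m, 2, sd)),
             stringsAsFactors = FALSE)
}

#' One-way repeated-measures ANOVA across wavelengths
#'
#' Treats the BP types as subjects measured once per wavelength and tests
#' the wavelength main effect with the standard two-way additive
#' decomposition: `SS_total = SS_channel + SS_subject + SS_error`,
#' `F = MS_channel / MS_error` on `(c - 1, (c - 1)(r - 1))` degrees of
#' freedom.
#'
#' @param m An `r2_matrix` (subjects in rows, channels in columns).
#' @return An object of class `rm_anova`: list with `F`, `df_num`,
#'   `df_den`, `p`, `ms_error`, `column_means` and the `ss` decomposition.
#'   A zero error mean square yields `F = Inf` with a warning.
#' @export
#' @examples
#' rm_anova_oneway(reference_r2_matrix())
rm_anova_oneway <- function(m) {
  check_r2_matrix(m)
  r <- nrow(m); c <- ncol(m)
  gm <- mean(m)
  col_means <- colMeans(m)
  row_means <- rowMeans(m)
  ss_col <- r * sum((col_means - gm)^2)
  ss_row <- c * sum((row_means - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_col - ss_row
  df_num <- c - 1L
  df_den <- (c - 1L) * (r - 1L)
  ms_err <- ss_err / df_den
  if (ms_err <= .Machine$double.eps * ss_tot) {
    warning("zero error mean square: F is infinite", call. = FALSE)
    f <- if (ss_col > 0) Inf else 0
    p <- if (ss_col > 0) 0 else 1
  } else {
    f <- (ss_col / df_num) / ms_err
    p <- pf(f, df_num, df_den, lower.tail = FALSE)
  }
  out <- list(F = f, df_num = df_num, df_den = df_den, p = p,
              ms_error = ms_err, column_means = col_means,
              ss = c(channel = ss_col, subject = ss_row, error = ss_err,
                     total = ss_tot),
              n_subjects = r)
  class(out) <- "rm_anova"
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> wavelength effect: F(%d,%d) = %.2f, p = %.3f\n",
              x$df_num, x$df_den, x$F, x$p))
  cat("  column means:", paste(sprintf("%s %.3f", names(x$column_means),
                                       x$column_means), collapse = ", "), "\n")
  invisible(x)
}

#' Tukey HSD comparison of wavelengths
#'
#' All-pairs comparison following the repeated-measures ANOVA: for channels
#' i and j, `q = |mean_i - mean_j| / sqrt(MS_error / r)` is referred to the
#' studentized range distribution with `c` groups and the ANOVA error
#' degrees of freedom.
#'
#' @param m The `r2_matrix` that was analysed.
#' @param anova Optional [rm_anova_oneway()] result for `m` (computed if
#'   missing).
#' @param alpha Familywise significance level (default 0.05).
#' @return A data.frame with one row per channel pair: `pair`, `diff`,
#'   `q`, `p_adj`, `significant`, `direction` (e.g. `"G < B"` for
#'   significant pairs, `""` otherwise).
#' @export
#' @examples
#' tukey_hsd_channels(reference_r2_matrix())
tukey_hsd_channels <- function(m, anova = NULL, alpha = 0.05) {
  check_r2_matrix(m)
  anova <- anova %||% rm_anova_oneway(m)
  cm <- anova$column_means
  r <- anova$n_subjects
  c <- length(cm)
  se <- sqrt(anova$ms_error / r)
  qcrit <- qtukey(1 - alpha, c, anova$df_den)
  pairs <- utils::combn(names(cm), 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    diff <- cm[[i]] - cm[[j]]
    q <- abs(diff) / se
    sig <- is.finite(q) && q > qcrit
    data.frame(
      pair = paste(i, j, sep = "-"),
      diff = diff,
      q = q,
      p_adj = ptukey(q, c, anova$df_den, lower.tail = FALSE),
      significant = sig,
      direction = if (sig) {
        if (diff < 0) paste(i, "<", j) else paste(j, "<", i)
      } else "",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "q_critical") <- qcrit
  attr(out, "alpha") <- alpha
  out
}

#' Bland-Altman agreement statistics
#'
#' Differences are `estimated - measured`. Reports the fixed bias M (mean
#' difference), its SD, the 95% limits of agreement `M +/- 1.96 SD`, the
#' mean and SD of the absolute error, and counts of absolute errors in the
#' classes [0,5), [5,10), [10,15) and >= 15 mmHg.
#'
#' @param estimated,measured Equal-length numeric vectors (mmHg), n >= 2.
#' @param bin_edges Lower edges of the absolute-error classes (the last
#'   class is open-ended). Default `c(0, 5, 10, 15)`.
#' @return An object of class `bland_altman`.
#' @export
#' @examples
#' bland_altman(c(120, 118, 131), c(118, 121, 128))
bland_altman <- function(estimated, measured, bin_edges = c(0, 5, 10, 15)) {
  if (length(estimated) != length(measured)) {
    abort_ppgbp("`estimated` and `measured` must have equal length",
                "ppgbp_schema_error")
  }
  n <- length(estimated)
  if (n < 2L) {
    abort_ppgbp("need at least 2 pairs", "ppgbp_degenerate_input")
  }
  d <- estimated - measured
  bias <- mean(d)
  sdd <- sd(d)
  ad <- abs(d)
  counts <- as.integer(table(cut(ad, c(bin_edges, Inf), right = FALSE)))
  names(counts) <- c(paste0("[", head(bin_edges, -1), ",",
                            bin_edges[-1], ")"),
                     paste0(">=", bin_edges[length(bin_edges)]))
  out <- list(bias_M = bias, sd_diff = sdd,
              loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
              mae = mean(ad), sd_abs = sd(ad),
              class_counts = counts, n = n, differences = d)
  class(out) <- "bland_altman"
  out
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d: bias M = %.2f mmHg, SD = %.2f, LoA [%.2f, %.2f]\n",
              x$n, x$bias_M, x$sd_diff, x$loa_low, x$loa_high))
  cat(sprintf("  |error|: mean %.2f, SD %.2f; classes: %s\n", x$mae, x$sd_abs,
              paste(names(x$class_counts), x$class_counts, sep = "=",
                    collapse = " ")))
  invisible(x)
}

#' Paired t test (closed form)
#'
#' `t = mean(d) / (SD(d) / sqrt(n))` with `d = x - y` and `n - 1` degrees
#' of freedom; the p-value is two-sided.
#'
#' @param x,y Equal-length numeric vectors, n >= 2, with non-degenerate
#'   differences.
#' @return A list `t`, `df`, `p`, `mean_diff`.
#' @export
#' @examples
#' paired_t(c(2, 4, 6, 8), c(1, 2, 3, 4))
paired_t <- function(x, y) {
  if (length(x) != length(y)) {
    abort_ppgbp("`x` and `y` must have equal length", "ppgbp_schema_error")
  }
  n <- length(x)
  if (n < 2L) abort_ppgbp("need at least 2 pairs", "ppgbp_degenerate_input")
  d <- x - y
  sdd <- sd(d)
  if (sdd == 0) {
    abort_ppgbp("zero-variance differences: t undefined",
                "ppgbp_degenerate_input")
  }
  tval <- mean(d) / (sdd / sqrt(n))
  list(t = tval, df = n - 1L, p = 2 * pt(abs(tval), n - 1L, lower.tail = FALSE),
       mean_diff = mean(d))
}

#' Geometric mean regression
#'
#' Symmetric (reduced major axis) regression used for calibration scatter
#' plots: `slope = sign(corr(x, y)) * SD(y) / SD(x)`,
#' `intercept = mean(y) - slope * mean(x)`.
#'
#' @param x,y Numeric vectors with at least 3 points and nonzero spread.
#' @return A list `slope`, `intercept`, `r` (Pearson correlation).
#' @export
#' @examples
#' gm_regression(1:5, 2 * (1:5) + 1)
gm_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort_ppgbp("need equal-length vectors with at least 3 points",
                "ppgbp_degenerate_input")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort_ppgbp("zero variance in x or y", "ppgbp_degenerate_input")
  }
  r <- cor(x, y)
  slope <- sign(r) * sd(y) / sd(x)
  if (slope == 0) slope <- sd(y) / sd(x)  # r exactly 0: conventionally positive
  list(slope = slope, intercept = mean(y) - slope * mean(x), r = r)
}

#' Shapiro-Wilk normality check of regression residuals
#'
#' Thin wrapper around [stats::shapiro.test()] with the size guard the test
#' requires (3 <= n <= 5000).
#'
#' @param residuals Numeric vector of residuals.
#' @return A list `W`, `p`.
#' @export
normality_check <- function(residuals) {
  n <- length(residuals)
  if (n < 3L || n > 5000L) {
    abort_ppgbp("Shapiro-Wilk requires 3 <= n <= 5000",
                "ppgbp_unsupported_size")
  }
  sw <- shapiro.test(residuals)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Agreement report for a set of BP estimates
#'
#' Runs [bland_altman()] per BP type and channel on the long estimate table
#' from [estimate_bp()].
#'
#' @param estimates Data.frame with `bp_type`, `channel`, `estimated`,
#'   `measured`.
#' @return A named list of [bland_altman()] reports keyed
#'   `"<bp_type>.<channel>"`.
#' @export
agreement_by_cell <- function(estimates) {
  need <- c("bp_type", "channel", "estimated", "measured")
  if (!all(need %in% names(estimates))) {
    abort_ppgbp("estimates need bp_type/channel/estimated/measured columns",
                "ppgbp_schema_error")
  }
  out <- list()
  for (bt in unique(estimates$bp_type)) {
    for (ch in unique(estimates$channel)) {
      e <- estimates[estimates$bp_type == bt & estimates$channel == ch, ]
      if (nrow(e) >= 2L) {
        out[[paste(bt, ch, sep = ".")]] <- bland_altman(e$estimated, e$measured)
      }
    }
  }
  out
}
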