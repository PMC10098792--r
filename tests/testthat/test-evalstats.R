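# Wavelength comparison and agreement statistics.

test_that("per-wavelength mean R^2 matches the published summary", {
  mr <- mean_r2_by_channel(reference_r2_matrix())
  expect_equal(round(mr$mean[mr$channel == "B"], 3), 0.580)
  expect_equal(round(mr$mean[mr$channel == "G"], 3), 0.499)
  expect_equal(round(mr$mean[mr$channel == "R"], 3), 0.560)
  expect_equal(round(mr$mean[mr$channel == "NIR"], 3), 0.567)

  m <- matrix(0.5, 3, 4, dimnames = list(c("SBP", "DBP", "MAP"),
                                         c("B", "G", "R", "NIR")))
  mr2 <- mean_r2_by_channel(m)
  expect_true(all(mr2$mean == 0.5) && all(mr2$sd == 0))

  m[2, 3] <- NA
  expect_error(mean_r2_by_channel(m), class = "ppgbp_incomplete_matrix")
})

test_that("repeated-measures ANOVA reproduces the published F(3,6)", {
  a <- rm_anova_oneway(reference_r2_matrix())
  expect_equal(a$df_num, 3L)
  expect_equal(a$df_den, 6L)
  expect_equal(a$F, 18.74, tolerance = 0.1)
  expect_lt(abs(a$p - 0.002), 5e-4)
  # column means agree with mean_r2_by_channel
  expect_equal(unname(a$column_means),
               mean_r2_by_channel(reference_r2_matrix())$mean,
               tolerance = 1e-12)
})

test_that("ANOVA SS decomposition conserves total SS and matches aov()", {
  set.seed(7)
  for (rep in 1:10) {
    m <- matrix(runif(12, 0.3, 0.9), 3, 4,
                dimnames = list(c("SBP", "DBP", "MAP"),
                                c("B", "G", "R", "NIR")))
    a <- rm_anova_oneway(m)
    expect_equal(sum(a$ss[c("channel", "subject", "error")]),
                 a$ss[["total"]], tolerance = 1e-10)

    # brute-force sums of squared deviations, computed independently
    gm <- mean(m)
    ss_col <- 0
    for (j in 1:4) ss_col <- ss_col + 3 * (mean(m[, j]) - gm)^2
    expect_equal(a$ss[["channel"]], ss_col, tolerance = 1e-12)

    long <- expand.grid(subj = rownames(m), ch = colnames(m))
    long$y <- as.vector(m)
    o <- summary(aov(y ~ ch + Error(subj), data = long))
    ftab <- o[["Error: Within"]][[1]]
    expect_equal(a$F, ftab["ch", "F value"], tolerance = 1e-8)
    expect_equal(a$p, ftab["ch", "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("zero-dispersion matrices give F = 0 or a flagged infinite F", {
  same_cols <- matrix(rep(c(0.4, 0.5, 0.6), 4), 3, 4,
                      dimnames = list(c("SBP", "DBP", "MAP"),
                                      c("B", "G", "R", "NIR")))
  expect_warning(a0 <- rm_anova_oneway(same_cols), "infinite|zero")
  expect_equal(a0$F, 0)

  shifted <- same_cols + matrix(rep(c(0, 0.1, 0.2, 0.3), each = 3), 3, 4)
  expect_warning(ai <- rm_anova_oneway(shifted), "infinite")
  expect_true(is.infinite(ai$F))
})

test_that("Tukey HSD flags green below the other three wavelengths only", {
  tk <- tukey_hsd_channels(reference_r2_matrix(), alpha = 0.05)
  sig <- tk[tk$significant, ]
  expect_setequal(sig$direction, c("G < B", "G < R", "G < NIR"))
  expect_equal(nrow(sig), 3L)

  # no dispersion between columns -> nothing significant
  same <- matrix(rep(c(0.4, 0.5, 0.6), 4), 3, 4,
                 dimnames = list(c("SBP", "DBP", "MAP"),
                                 c("B", "G", "R", "NIR")))
  suppressWarnings(tk0 <- tukey_hsd_channels(same))
  expect_false(any(tk0$significant))

  # extreme separation is always flagged
  set.seed(1)
  m <- matrix(0.5 + rnorm(12, 0, 0.01), 3, 4,
              dimnames = list(c("SBP", "DBP", "MAP"),
                              c("B", "G", "R", "NIR")))
  a <- rm_anova_oneway(m)
  m[, "G"] <- m[, "G"] + 100 * sqrt(a$ms_error)
  tk2 <- tukey_hsd_channels(m)
  expect_true(all(tk2$significant[grepl("G", tk2$pair)]))
})

test_that("Bland-Altman bias, limits and error classes follow the definitions", {
  x <- c(118, 125, 109, 131)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias_M, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(unname(ba0$class_counts), c(4L, 0L, 0L, 0L))

  ba5 <- bland_altman(x + 5, x)
  expect_equal(ba5$bias_M, 5)
  expect_equal(ba5$loa_low, 5)
  expect_equal(ba5$loa_high, 5)

  bab <- bland_altman(x + c(3, -7, 12, 20), x)
  expect_equal(unname(bab$class_counts), c(1L, 1L, 1L, 1L))
  expect_equal(sum(bab$class_counts), bab$n)
  expect_lte(bab$loa_low, bab$bias_M)
  expect_gte(bab$loa_high, bab$bias_M)

  expect_error(bland_altman(1:3, 1:4), class = "ppgbp_schema_error")
})

test_that("limits of agreement contain ~95% of large Gaussian samples", {
  set.seed(99)
  est <- rnorm(10000, 120, 8)
  meas <- est + rnorm(10000, 1.5, 4)
  ba <- bland_altman(est, meas)
  inside <- mean(ba$differences >= ba$loa_low & ba$differences <= ba$loa_high)
  expect_gte(inside, 0.94)
  expect_lte(inside, 0.97)
})

test_that("paired t matches the closed form and t.test", {
  # d = (1, 2, 3, 4): t = 2.5 / (1.2910 / 2) = 3.873
  r <- paired_t(c(2, 4, 6, 8), c(1, 2, 3, 4))
  expect_equal(round(r$t, 3), 3.873)
  o <- t.test(c(2, 4, 6, 8), c(1, 2, 3, 4), paired = TRUE)
  expect_equal(r$t, unname(o$statistic), tolerance = 1e-10)
  expect_equal(r$p, o$p.value, tolerance = 1e-10)

  # antisymmetry
  rr <- paired_t(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(rr$t, -r$t, tolerance = 1e-12)
  expect_equal(rr$p, r$p, tolerance = 1e-12)

  expect_error(paired_t(1:4 + 2, 1:4), class = "ppgbp_degenerate_input")
})

test_that("geometric mean regression follows the SD-ratio rule", {
  x <- c(1, 2, 3, 4, 5)
  g1 <- gm_regression(x, x)
  expect_equal(g1$slope, 1, tolerance = 1e-12)
  expect_equal(g1$intercept, 0, tolerance = 1e-12)

  g2 <- gm_regression(x, 2 * x + 1)
  expect_equal(g2$slope, 2, tolerance = 1e-12)
  expect_equal(g2$intercept, 1, tolerance = 1e-12)

  set.seed(5)
  xa <- rnorm(50); ya <- -2 * xa + rnorm(50, 0, 0.5)
  ga <- gm_regression(xa, ya)
  expect_lt(ga$r, 0)
  expect_equal(ga$slope, -sd(ya) / sd(xa), tolerance = 1e-12)

  expect_error(gm_regression(rep(1, 5), 1:5),
               class = "ppgbp_degenerate_input")
})

test_that("Shapiro-Wilk wrapper behaves on clean, bimodal and permuted input", {
  set.seed(11)
  clean <- rnorm(42, 0, 1e-8)  # residuals of a numerically exact fit
  expect_gt(normality_check(clean)$p, 0.01)

  bimodal <- rep(c(-1, 1), 21)
  expect_lt(normality_check(bimodal + rnorm(42, 0, 0.01))$p, 0.05)

  r <- rnorm(42)
  w1 <- normality_check(r)$W
  w2 <- normality_check(sample(r))$W
  expect_equal(w1, w2, tolerance = 1e-12)

  expect_error(normality_check(c(1, 2)), class = "ppgbp_unsupported_size")
})
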