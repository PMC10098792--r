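# Delta-ln transform, pooled OLS fit, back-transformation, MAP rule.

test_that("delta_ln is the log-ratio and inverts through exp", {
  expect_equal(delta_ln(5.3, 5.3), 0)
  # frozen from direct arithmetic: log(121.6 / 112.3)
  expect_equal(delta_ln(121.6, 112.3), 0.07956311, tolerance = 1e-7)
  set.seed(1)
  v <- runif(20, 0.1, 200); r <- runif(20, 0.1, 200)
  expect_equal(exp(delta_ln(v, r)) * r, v, tolerance = 1e-12)
  expect_error(delta_ln(-1, 2), class = "ppgbp_invalid_parameter")
  expect_error(delta_ln(1, 0), class = "ppgbp_invalid_parameter")
})

test_that("one-third MAP reproduces the published group means", {
  expect_equal(round(map_one_third(112.3, 68.5), 1), 83.1)
  expect_equal(round(map_one_third(121.6, 77.9), 1), 92.5)
  expect_equal(map_one_third(90, 60), 70.0)
  expect_error(map_one_third(80, 80), class = "ppgbp_invalid_pressures")
  expect_error(map_one_third(60, 90), class = "ppgbp_invalid_pressures")
})

test_that("delta table has 3 rows per participant x channel, zero when static", {
  s <- generate_session(generator_config(n_participants = 14, seed = 2),
                        make_traces = FALSE)
  d <- build_delta_table(s$truth$features, s$cuff)
  expect_equal(nrow(d), 14 * 4 * 3)
  expect_equal(sum(d$channel == "NIR"), 42)  # pooled n per wavelength

  # all conditions identical to BL1 -> every delta is zero
  hs <- hand_session(hr = rep(70, 4), mnpv = rep(0.02, 4),
                     bp = list(SBP = rep(110, 4), DBP = rep(70, 4),
                               MAP = rep(110 / 3 + 70 * 2 / 3, 4)))
  d0 <- build_delta_table(hs$features, hs$cuff)
  expect_equal(nrow(d0), 3)
  expect_true(all(abs(as.matrix(d0[, 4:8])) < 1e-14))

  # missing BL1 is an error; a missing other condition drops the row
  no_ref <- hs
  no_ref$cuff <- no_ref$cuff[no_ref$cuff$condition != "BL1", ]
  expect_error(build_delta_table(no_ref$features, no_ref$cuff),
               class = "ppgbp_missing_reference")
  partial <- hs
  partial$features <- partial$features[partial$features$condition != "MA2", ]
  expect_warning(dp <- build_delta_table(partial$features, partial$cuff),
                 "MA2")
  expect_equal(nrow(dp), 2)
})

test_that("noiseless generator coefficients are recovered to 1e-8", {
  s <- generate_session(generator_config(noise_sd_lnBP = 0, seed = 4),
                        make_traces = FALSE)
  d <- build_delta_table(s$truth$features, s$cuff)
  f <- fit_bp_model(d, "SBP", "NIR")
  expect_equal(f$a, 0.373, tolerance = 1e-8)
  expect_equal(f$b, -0.012, tolerance = 1e-8)
  expect_equal(f$c, 0.001, tolerance = 1e-8)
  expect_equal(f$R2, 1, tolerance = 1e-10)
  expect_equal(f$n, 42)
})

test_that("normal-equations OLS agrees with lm() on random data", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(8:30, 1)
    d <- data.frame(participant = sprintf("P%02d", seq_len(n)),
                    condition = "MA1", channel = "NIR",
                    dln_HR = rnorm(n, 0, 0.2),
                    dln_mNPV = rnorm(n, 0, 0.4))
    d$dln_SBP <- 0.3 * d$dln_HR - 0.05 * d$dln_mNPV + rnorm(n, 0, 0.05)
    d$dln_DBP <- d$dln_SBP; d$dln_MAP <- d$dln_SBP
    f <- fit_bp_model(d, "SBP", "NIR")
    o <- summary(lm(dln_SBP ~ dln_HR + dln_mNPV, data = d))
    expect_equal(f$a, unname(o$coefficients["dln_HR", 1]), tolerance = 1e-8)
    expect_equal(f$b, unname(o$coefficients["dln_mNPV", 1]), tolerance = 1e-8)
    expect_equal(f$c, unname(o$coefficients["(Intercept)", 1]),
                 tolerance = 1e-8)
    expect_equal(f$R2, o$r.squared, tolerance = 1e-10)
    expect_equal(f$p_a, unname(o$coefficients["dln_HR", 4]),
                 tolerance = 1e-8)
    expect_equal(f$overall_p,
                 unname(pf(o$fstatistic[1], o$fstatistic[2], o$fstatistic[3],
                           lower.tail = FALSE)), tolerance = 1e-8)
    # single-response OLS identity: R^2 = cor(fitted, observed)^2
    expect_equal(f$R2, cor(f$fitted, d$dln_SBP)^2, tolerance = 1e-10)
  }
})

test_that("degenerate designs raise instead of returning silent zeros", {
  d <- data.frame(participant = sprintf("P%02d", 1:8), condition = "MA1",
                  channel = "NIR", dln_HR = rnorm(8), dln_mNPV = rnorm(8),
                  dln_SBP = 0, dln_DBP = 0, dln_MAP = 0)
  expect_error(fit_bp_model(d, "SBP", "NIR"),
               class = "ppgbp_degenerate_input")
  d2 <- d
  d2$dln_SBP <- rnorm(8)
  d2$dln_mNPV <- d2$dln_HR  # perfectly collinear predictors
  expect_error(fit_bp_model(d2, "SBP", "NIR"),
               class = "ppgbp_singular_design")
})

test_that("standardized betas are invariant to rescaling a predictor", {
  set.seed(3)
  n <- 30
  d <- data.frame(participant = sprintf("P%02d", seq_len(n)),
                  condition = "MA1", channel = "NIR",
                  dln_HR = rnorm(n, 0, 0.2), dln_mNPV = rnorm(n, 0, 0.4))
  d$dln_SBP <- 0.3 * d$dln_HR - 0.05 * d$dln_mNPV + rnorm(n, 0, 0.03)
  d$dln_DBP <- d$dln_SBP; d$dln_MAP <- d$dln_SBP
  f1 <- fit_bp_model(d, "SBP", "NIR")
  d2 <- d; d2$dln_HR <- 17 * d2$dln_HR
  f2 <- fit_bp_model(d2, "SBP", "NIR")
  expect_equal(f1$std_beta_a, f2$std_beta_a, tolerance = 1e-10)
  expect_equal(f1$std_beta_b, f2$std_beta_b, tolerance = 1e-10)
})

test_that("estimate_bp back-transforms through the BL1 reference", {
  # zero deltas with zero intercept return the BL1 value exactly
  hs <- hand_session(hr = rep(70, 4), mnpv = rep(0.02, 4),
                     bp = list(SBP = rep(110, 4), DBP = rep(70, 4),
                               MAP = rep(110 / 3 + 70 * 2 / 3, 4)))
  d0 <- build_delta_table(hs$features, hs$cuff)
  fit0 <- structure(list(bp_type = "SBP", channel = "NIR",
                         a = 0.4, b = -0.1, c = 0), class = "bp_fit")
  est0 <- estimate_bp(d0, hs$cuff, fit0)
  expect_equal(est0$estimated, rep(110, 3), tolerance = 1e-12)

  # worked inverse of the delta_ln example
  expect_equal(112.3 * exp(delta_ln(121.6, 112.3)), 121.6, tolerance = 1e-10)

  # noiseless self-consistent session reproduces the cuff values
  s <- generate_session(generator_config(noise_sd_lnBP = 0, seed = 6),
                        make_traces = FALSE)
  d <- build_delta_table(s$truth$features, s$cuff)
  fits <- fit_all_models(d)
  est <- estimate_bp(d, s$cuff, fits)
  expect_lt(max(abs(est$estimated - est$measured) / est$measured), 1e-6)
  expect_true(all(est$estimated > 0))
})

test_that("coefficient errors shrink with more participants (consistency)", {
  errs <- function(n, seeds) {
    vapply(seeds, function(sd) {
      s <- generate_session(generator_config(n_participants = n,
                                             noise_sd_lnBP = 0.03,
                                             seed = sd),
                            make_traces = FALSE)
      f <- fit_bp_model(build_delta_table(s$truth$features, s$cuff),
                        "SBP", "NIR")
      abs(f$a - 0.373)
    }, numeric(1))
  }
  e14 <- errs(14, 1:12)
  e140 <- errs(140, 1:12)
  expect_lt(mean(e140), mean(e14))
})
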