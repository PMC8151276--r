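test_that("BRET ratio is plain division with domain guards", {
  expect_equal(bret_ratio(10000, 10000), 1.0)
  expect_equal(bret_ratio(3000, 10000), 0.3)
  expect_error(bret_ratio(3000, 0), "donor")
  expect_error(bret_ratio(-1, 10000), "acceptor")
})

test_that("fold response and the inclusive 1.5 boundary", {
  fr <- fold_response(0.30, 0.15)
  expect_equal(fr$fold_response, 2.0); expect_true(fr$positive)
  fr <- fold_response(0.2, 0.2)
  expect_equal(fr$fold_response, 1.0); expect_false(fr$positive)
  fr <- fold_response(0.15, 0.10)
  expect_equal(fr$fold_response, 1.5); expect_true(fr$positive)  # inclusive
  expect_false(fold_response(0.149999, 0.1)$positive)
  expect_error(fold_response(0.3, 0), "control")
})

test_that("signal/noise equals the hand computation with sample SD", {
  expect_equal(signal_noise(0.17, c(0.09, 0.10, 0.11)), 7.0)
  expect_equal(signal_noise(0.10, c(0.09, 0.10, 0.11)), 0)
  expect_warning(s <- signal_noise(0.17, c(0.1, 0.1)), "zero spread")
  expect_true(is.na(s))
  expect_error(signal_noise(0.17, 0.1), "replicates")
})

test_that("Eq.-style signal/noise matches an independent recomputation on fixtures", {
  set.seed(12)
  for (i in 1:20) {
    tracer <- runif(1, 0.1, 0.5)
    ctrl <- runif(sample(2:6, 1), 0.05, 0.15)
    oracle <- (tracer - sum(ctrl) / length(ctrl)) /
      sqrt(sum((ctrl - mean(ctrl))^2) / (length(ctrl) - 1))
    expect_equal(signal_noise(tracer, ctrl), oracle)
  }
})

test_that("screen summary calls planted binders and only them", {
  cfg <- synthetic_bret_config(true_fold_response = 2.0, background_bret = 0.1,
                               noise_sd = 0.005, n_replicates = 3,
                               concentrations = c(100, 1000), seed = 31)
  truth <- data.frame(construct = sprintf("G%02d", 1:12), tracer = "T1",
                      bound = rep(c(TRUE, FALSE), c(5, 7)))
  res <- screen_summary(generate_bret_plate(cfg, truth))
  pos <- unique(res$construct[res$positive])
  expect_setequal(pos, sprintf("G%02d", 1:5))
  prof <- attr(res, "profile")
  expect_setequal(prof$retained, sprintf("G%02d", 1:5))  # positive at 100 nM

  # all-null plate: zero positives at both concentrations
  truth0 <- truth; truth0$bound <- FALSE
  res0 <- screen_summary(generate_bret_plate(cfg, truth0))
  expect_equal(sum(res0$positive), 0)

  # missing paired condition -> skipped with warning
  plate <- generate_bret_plate(cfg, truth)
  broken <- plate[!(plate$construct == "G01" &
                      plate$condition == "tracer_plus_competitor" &
                      plate$concentration_nM == 100), ]
  expect_warning(res_b <- screen_summary(broken), "G01")
  expect_false("G01" %in% res_b$construct[res_b$concentration_nM == 100])
  expect_true("G01" %in% res_b$construct[res_b$concentration_nM == 1000])
})

test_that("fold response is scale-invariant and call-monotone", {
  cfg <- synthetic_bret_config(noise_sd = 0.005, n_replicates = 3,
                               concentrations = 1000, seed = 8)
  truth <- data.frame(construct = c("A", "B"), tracer = "T",
                      bound = c(TRUE, FALSE))
  plate <- generate_bret_plate(cfg, truth)
  res1 <- screen_summary(plate)
  plate2 <- plate
  plate2$donor_em <- plate2$donor_em * 7.3
  plate2$acceptor_em <- plate2$acceptor_em * 7.3
  res2 <- screen_summary(plate2)
  expect_equal(res1$fold_response, res2$fold_response)
  expect_identical(res1$positive, res2$positive)

  # increasing tracer BRET with fixed control never flips positive -> negative
  folds <- fold_response(seq(0.15, 0.60, by = 0.05), 0.1)
  expect_true(all(diff(folds$positive) >= 0))
})

test_that("noise-free saturation fit recovers the hyperbola exactly", {
  cfg <- synthetic_bret_config(noise_sd = 0, bmax = 0.2, ec50 = 50,
                               n_replicates = 2, seed = 1)
  fit <- fit_saturation(generate_saturation_series(cfg))
  expect_true(fit$converged)
  expect_equal(fit$bmax, 0.2, tolerance = 1e-6)
  expect_equal(fit$ec50, 50, tolerance = 1e-6)
  # corrected value at c = ec50 equals bmax/2
  cor50 <- fit$corrected$corrected_bret[fit$corrected$concentration_nM == 62.5]
  expect_equal(cor50, 0.2 * 62.5 / (50 + 62.5), tolerance = 1e-9)
})

test_that("degenerate series yields a fit-failure result, never a crash", {
  cfg <- synthetic_bret_config(noise_sd = 0, bmax = 1e-9, ec50 = 50,
                               n_replicates = 1, seed = 1)
  ser <- generate_saturation_series(cfg)
  # force all-negative corrected signal
  ser$acceptor_em[ser$condition == "tracer_alone"] <-
    ser$acceptor_em[ser$condition == "tracer_alone"] * 0.5
  fit <- fit_saturation(ser)
  expect_false(fit$converged)
  expect_true(is.na(fit$ec50))
})
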