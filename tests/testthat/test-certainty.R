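test_that("certainty binning partitions [0.5, 1] into 10 left-closed bins", {
  expect_identical(certainty_bin(0.52)$index, 1L)
  expect_identical(certainty_bin(0.55)$index, 2L) # boundary goes up
  expect_identical(certainty_bin(1)$index, 10L)   # top bin closed
  expect_error(certainty_bin(0.49), "0.5")
  expect_error(certainty_bin(1.01), "0.5")
  # dense sweep against an integer-arithmetic oracle
  ppm <- seq(500L, 1000L, by = 1L) # p in 1/1000 units
  oracle <- pmin((ppm - 500L) %/% 50L + 1L, 10L)
  got <- certainty_bin(ppm / 1000)$index
  expect_identical(got, as.integer(oracle))
  expect_identical(sort(unique(got)), 1:10)
})

test_that("Fisher z comparison matches the closed form", {
  set.seed(5)
  base <- rnorm(64)
  maps <- cbind(ssvep = base, swift = rnorm(64),
                im_11.3 = base + rnorm(64, sd = 0.6))
  tc <- topo_correlation_compare(maps)
  r1 <- cor(maps[, 3], maps[, 1]); r2 <- cor(maps[, 3], maps[, 2])
  expect_equal(tc$z, (atanh(r1) - atanh(r2)) / sqrt(2 / 61), tolerance = 1e-12)
  # the reference example: r1 = 0.8, r2 = 0.3, n = 64
  z_ref <- (atanh(0.8) - atanh(0.3)) / sqrt(2 / 61)
  expect_equal(z_ref, 4.356, tolerance = 1e-3)
  # identical maps: r = 1 is degenerate for atanh, so compare two equal
  # correlations instead: z must be 0
  maps2 <- cbind(ssvep = base, swift = base, im = base + rnorm(64))
  tc2 <- topo_correlation_compare(maps2)
  expect_equal(tc2$z, 0, tolerance = 1e-12)
  expect_equal(tc2$r_im_ssvep, tc2$r_im_swift)
  expect_error(topo_correlation_compare(
    cbind(ssvep = rep(1, 8), swift = rnorm(8), im = rnorm(8))),
    "zero-variance")
  expect_error(topo_correlation_compare(maps[1:3, ]), "4 channels")
})

test_that("simulated topographies correlate IMs with SSVEP, not SWIFT", {
  st <- session_snr_table(test_params(), 3, 10, foi = test_foi(),
                          preprocess = FALSE, seed = 31)
  maps <- snr_scalp_maps(st$snr)
  tc <- topo_correlation_compare(maps)
  expect_identical(nrow(tc), 4L)
  expect_true(all(tc$z > 0))
})

test_that("the certainty LRT recovers directions on a simulated session", {
  st <- session_snr_table(test_params(), 4, 14, foi = test_foi(),
                          preprocess = FALSE, seed = 77)
  sw <- fit_certainty_effect(st$snr, level = 1, frequency = 1.3,
                             re_cov = "diag")
  expect_s3_class(sw, "lme_result")
  expect_identical(sw$direction, "-")
  expect_lt(sw$p_raw, 0.01)
  expect_gte(sw$chi2, 0)
  im <- fit_certainty_effect(st$snr, level = 2, category = "im",
                             re_cov = "diag")
  expect_identical(im$direction, "+")
  expect_lt(im$p_raw, 0.01)
  # level-3 antisymmetry: swapping reference and category flips the sign
  ab <- interaction_contrast(st$snr, "im", reference = "ssvep",
                             re_cov = "diag")
  ba <- interaction_contrast(st$snr, "ssvep", reference = "im",
                             re_cov = "diag")
  expect_equal(unname(ab$estimate), -unname(ba$estimate), tolerance = 0.02)
  expect_identical(ab$direction, "+")
})

test_that("the LRT statistic is invariant to affine predictor rescaling", {
  st <- session_snr_table(test_params(), 3, 10, foi = test_foi(),
                          preprocess = FALSE, seed = 5)
  r1 <- fit_certainty_effect(st$snr, level = 1, frequency = 1.3,
                             re_cov = "diag")
  st2 <- st
  st2$snr$certainty_bin <- 10 * st2$snr$certainty_bin + 3
  r2 <- fit_certainty_effect(st2$snr, level = 1, frequency = 1.3,
                             re_cov = "diag")
  expect_equal(r1$chi2, r2$chi2, tolerance = 0.05)
  expect_equal(r1$estimate, 10 * r2$estimate, tolerance = 0.01)
})

test_that("non-positive SNR is rejected rather than silently logged", {
  st <- data.frame(participant = 1, trial = 1, channel = "Oz", freq = 1.3,
                   role = "swift", certainty_bin = 3, snr = 0,
                   log2snr = -Inf)
  expect_error(fit_certainty_effect(st, 1, frequency = 1.3), "positive")
  rec <- eeg_recording(matrix(0, 2, 5000), fs = 500)
  expect_error(snr_table(rec, test_foi()), "non-positive|NaN|missing")
})

test_that("the per-frequency effect table applies BH across the family", {
  st <- session_snr_table(test_params(), 3, 10, foi = test_foi(),
                          preprocess = FALSE, seed = 8)
  tab <- certainty_effect_table(st$snr, frequencies = c(1.3, 10, 11.3),
                                re_cov = "diag")
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$p_fdr >= tab$p_raw))
  expect_identical(tab$role, c("swift", "ssvep", "im"))
})
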