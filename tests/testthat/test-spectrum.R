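test_that("preprocessing resamples, high-passes and re-references", {
  # 1000 Hz input halves its sample count
  set.seed(1)
  n <- 4000
  t1k <- (0:(n - 1)) / 1000
  x <- rbind(sin(2 * pi * 10 * t1k), cos(2 * pi * 10 * t1k) + 2,
             rnorm(n, sd = 0.1))
  rec <- eeg_recording(x, fs = 1000, cycle_onsets = c(1, 2001))
  out <- preprocess_eeg(rec)
  expect_identical(out$fs, 500)
  expect_identical(ncol(out$data), as.integer(n / 2))
  expect_identical(out$cycle_onsets, c(1L, 1001L))
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  expect_error(preprocess_eeg(eeg_recording(x, fs = 250)), "sampling rate")
})

test_that("the 0.6 Hz high-pass barely touches a 10 Hz tag", {
  t5 <- (0:4999) / 500
  x <- rbind(sin(2 * pi * 10 * t5), -sin(2 * pi * 10 * t5))
  out <- preprocess_eeg(eeg_recording(x, fs = 500))
  amp <- amplitude_spectrum(out)
  k <- round(10 / amp$resolution) + 1
  expect_gt(amp$amplitude[1, k], 0.99)
  # and DC / sub-cutoff content is crushed
  slow <- rbind(1 + sin(2 * pi * 0.1 * t5), -1 - sin(2 * pi * 0.1 * t5))
  outs <- preprocess_eeg(eeg_recording(slow, fs = 500))
  expect_lt(max(abs(outs$data)), 0.05)
})

test_that("amplitude spectra use the unit-sinusoid calibration", {
  t <- (0:24999) / 500
  x <- rbind(sin(2 * pi * 10 * t), 0.5 * sin(2 * pi * 1.3 * t))
  sp <- amplitude_spectrum(eeg_recording(x, fs = 500))
  expect_equal(sp$resolution, 0.02, tolerance = 1e-12)
  expect_equal(sp$amplitude[1, round(10 / 0.02) + 1], 1, tolerance = 1e-9)
  expect_equal(sp$amplitude[2, round(1.3 / 0.02) + 1], 0.5, tolerance = 1e-9)
})

test_that("amplitude spectra satisfy Parseval", {
  set.seed(4)
  x <- matrix(rnorm(2 * 5000), 2)
  sp <- amplitude_spectrum(eeg_recording(x, fs = 500))
  nb <- length(sp$freqs)
  pow <- sp$amplitude[, 1]^2 + sp$amplitude[, nb]^2 +
    rowSums(sp$amplitude[, 2:(nb - 1)]^2) / 2
  expect_equal(pow, rowMeans(x^2), tolerance = 1e-6)
})

test_that("neighbour-bin SNR matches hand-computed ratios", {
  freqs <- seq(0, 50, by = 0.02)
  flat <- structure(list(freqs = freqs,
                         amplitude = matrix(1, 2, length(freqs)),
                         resolution = 0.02, fs = 500,
                         labels = c("a", "b")),
                    class = "amplitude_spectrum")
  expect_equal(snr_at(flat, 10), c(1, 1), tolerance = 1e-12)
  peaked <- flat
  k <- round(10 / 0.02) + 1
  peaked$amplitude[, k] <- 10
  expect_equal(snr_at(peaked, 10), c(10, 10), tolerance = 1e-12)
  # the window is exactly 10 bins per side: bin 11 away has no effect,
  # bin 10 away does
  out11 <- flat; out11$amplitude[, k + 11] <- 100
  expect_equal(snr_at(out11, 10), c(1, 1), tolerance = 1e-12)
  out10 <- flat; out10$amplitude[, k - 10] <- 100
  expect_equal(snr_at(out10, 10), rep(1 / mean(c(rep(1, 19), 100)), 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # scale invariance
  scaled <- peaked; scaled$amplitude <- scaled$amplitude * 37.5
  expect_equal(snr_at(scaled, 10), snr_at(peaked, 10))
  expect_error(snr_at(flat, 10.013), "grid")
  expect_error(snr_at(flat, 0.1), "edge")
  expect_error(snr_at(flat, 49.96), "edge")
})

test_that("white-noise SNR is unbiased near 1", {
  set.seed(6)
  p <- test_params(a1 = 0, a2_base = 0, a2_slope = 0,
                   g_base = 0, g_slope = 0, noise_exponent = 0)
  vals <- c()
  for (s in 1:2) {
    sp <- amplitude_spectrum(simulate_trial(p, 0.75, seed = s))
    ks <- sample(which(sp$freqs > 1 & sp$freqs < 40), 500)
    vals <- c(vals, vapply(ks, function(k)
      snr_at(sp, sp$freqs[k])[sample(16, 1)], numeric(1)))
  }
  expect_gt(mean(vals), 0.95)
  expect_lt(mean(vals), 1.05)
})

test_that("intermodulation enumeration reproduces the canonical sets", {
  im <- enumerate_im(10, 1.3)
  expect_equal(im$freq, c(7.4, 8.7, 11.3, 12.6), tolerance = 1e-9)
  expect_true(all(im$order <= 3))
  im2 <- enumerate_im(10, 1.3, list(c(2, -1), c(2, 2)))
  expect_equal(im2$freq, c(18.7, 22.6), tolerance = 1e-9)
  expect_error(enumerate_im(10, 1.3, list(c(0, 1))), "harmonic")
  # 10 + 2 * 2.5 = 15 = 6 * 2.5 collides with an f2 harmonic
  expect_warning(out <- enumerate_im(10, 2.5, list(c(1, 2))), "colliding")
  expect_identical(nrow(out), 0L)
  expect_equal(attr(out, "collisions")$freq, 15)
  # a non-colliding off-grid pair passes through untouched
  expect_equal(enumerate_im(10, 2.2, list(c(1, 1)))$freq, 12.2)
})

test_that("frequency sets are grid-exact and role-labelled", {
  foi <- frequency_set(duration_s = 50)
  expect_setequal(foi$role, c("ssvep", "swift", "harmonic", "im"))
  expect_identical(sum(foi$role == "im"), 4L)
  expect_error(frequency_set(f2 = 1.31, duration_s = 10), "grid")
})

test_that("group significance is a BH-adjusted one-sample t-test vs 1", {
  d <- data.frame(participant = rep(1:5, 2), freq = rep(c(10, 12), each = 5),
                  snr = c(rep(1, 5), c(3, 4, 5, 3.5, 4.5)))
  gs <- group_significance(d, alpha = 0.01)
  expect_identical(gs$t[gs$freq == 10], 0)
  expect_false(gs$significant[gs$freq == 10])
  expect_true(gs$significant[gs$freq == 12])
  # hand-computed step-up adjustment
  expect_equal(p.adjust(c(0.001, 0.02, 0.04), method = "BH"),
               c(0.003, 0.03, 0.04), tolerance = 1e-12)
  expect_error(group_significance(
    data.frame(participant = 1, freq = 10, snr = 2)), ">= 2 participants")
})
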