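test_that("cycle counts follow the band-specific rule", {
  expect_equal(cycles_for_frequency(c(1, 5, 7)), c(3L, 3L, 3L))
  expect_equal(cycles_for_frequency(c(8, 10, 14)), c(5L, 5L, 5L))
  expect_equal(cycles_for_frequency(c(15, 20, 30)), c(7L, 7L, 7L))
  expect_equal(cycles_for_frequency(c(31, 40, 60)), c(10L, 10L, 10L))
  expect_error(cycles_for_frequency(0.5), "1, 60")
  expect_error(cycles_for_frequency(61), "1, 60")
})

test_that("the tapered wavelet has the documented shape and normalization", {
  w <- make_tapered_wavelet(10, fs = 250)
  expect_length(w, 125)                      # ~500 ms at 250 Hz
  center <- attr(w, "center")
  expect_equal(center, 63)
  expect_equal(Im(w[center]), 0)             # sin(0) = 0 at the center sample
  # Hanning weights match the closed form
  n <- 125
  h <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  expect_equal(Mod(w) * sum(h), h, tolerance = 1e-12, ignore_attr = TRUE)
  # odd length always
  for (f in c(3, 9, 13, 27, 55)) {
    expect_equal(length(make_tapered_wavelet(f, fs = 250)) %% 2, 1)
  }
  expect_error(make_tapered_wavelet(-1, fs = 250), "positive")
})

test_that("a unit cosine yields |coeff| = 0.5 and its phase at the requested time", {
  for (phi0 in c(-2.5, -0.7, 0, 1.1, 3)) {
    es <- epochs_from_traces(matrix(alpha_trace(phi0), 1))
    tf <- tfr_transform(es, tfr_spec(freqs = 10, times = -250),
                        channels = "POz", method = "direct")
    z <- tf$coeff[1, 1, 1, 1]
    expect_equal(Mod(z), 0.5, tolerance = 1e-3)
    expect_lt(abs(circ_diff(Arg(z), phi0)) * 180 / pi, 1)
  }
})

test_that("FFT convolution equals the direct tapered inner product", {
  set.seed(4)
  es <- epochs_from_traces(matrix(rnorm(5 * n_samp_std), 5),
                           channels = c("POz", "Oz"))
  spec <- tfr_spec(freqs = c(2, 10, 23, 47), times = seq(-800, 1800, 100))
  a <- tfr_transform(es, spec, method = "fft")
  b <- tfr_transform(es, spec, method = "direct")
  expect_identical(a$valid, b$valid)
  ok <- !is.na(a$coeff)
  rel <- Mod(a$coeff[ok] - b$coeff[ok]) / pmax(Mod(b$coeff[ok]), 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("log power scales exactly and has a floor guard", {
  set.seed(5)
  es <- epochs_from_traces(matrix(rnorm(3 * n_samp_std), 3))
  es2 <- es; es2$data <- es2$data * 2
  spec <- tfr_spec(freqs = c(5, 10, 40), times = seq(-500, 500, 250))
  lp1 <- log_power(tfr_transform(es, spec, channels = "POz"))
  lp2 <- log_power(tfr_transform(es2, spec, channels = "POz"))
  expect_equal(lp2 - lp1, array(2 * log(2), dim(lp1)), tolerance = 1e-9)
  # |coeff| = 1 -> 0; |coeff| = e -> 2 (epsilon negligible)
  expect_equal(log(Mod(1)^2 + 1e-20), 0, tolerance = 1e-12)
  # amplitude ratio 3 between trials -> log-power difference 2 ln 3
  es3 <- epochs_from_traces(rbind(alpha_trace(0), 3 * alpha_trace(0)))
  lp <- log_power(tfr_transform(es3, tfr_spec(10, -250), channels = "POz"))
  expect_equal(lp[2, 1, 1, 1] - lp[1, 1, 1, 1], 2 * log(3), tolerance = 1e-6)
})

test_that("phase follows the time-shift theorem and power ignores phase", {
  t_ms <- std_times()
  f0 <- 10; phi0 <- 0.3
  base <- cos(2 * pi * f0 * (t_ms + 250) / 1000 + phi0)
  delayed <- cos(2 * pi * f0 * (t_ms - 25 + 250) / 1000 + phi0)  # +25 ms delay
  es <- epochs_from_traces(rbind(base, delayed))
  tf <- tfr_transform(es, tfr_spec(freqs = f0, times = -250), channels = "POz")
  ph <- phase_angles(tf)[, 1, 1, 1]
  expect_equal(circ_diff(ph[2], ph[1]), -pi / 2, tolerance = 1e-3)
  lp <- log_power(tf)[, 1, 1, 1]
  expect_equal(lp[1], lp[2], tolerance = 1e-3)  # edge leakage differs slightly
  # pure cosine peak at center -> 0; pure sine -> -pi/2
  es2 <- epochs_from_traces(rbind(alpha_trace(0), alpha_trace(-pi / 2)))
  ph2 <- phase_angles(tfr_transform(es2, tfr_spec(f0, -250),
                                    channels = "POz"))[, 1, 1, 1]
  expect_equal(ph2[1], 0, tolerance = 2e-2)
  expect_equal(ph2[2], -pi / 2, tolerance = 2e-2)
})

test_that("windows that overrun the epoch are invalid, never zero-padded", {
  es <- epochs_from_traces(matrix(rnorm(n_samp_std), 1))
  tf <- tfr_transform(es, tfr_spec(freqs = c(2, 10), times = c(-900, 0, 1900)),
                      channels = "POz")
  # 2 Hz / 3 cycles = 1.5 s kernel: +/-750 ms does not fit at -900 or 1900 ms
  expect_false(tf$valid[1, 1])
  expect_true(tf$valid[1, 2])
  expect_false(tf$valid[1, 3])
  # 10 Hz / 5 cycles = 500 ms kernel: fits at 0, overruns at -900 and 1900
  expect_equal(tf$valid[2, ], c(FALSE, TRUE, FALSE))
  expect_true(all(is.na(log_power(tf)[1, 1, 1, c(1, 3)])))
  # 1 Hz / 3 cycles = 3 s kernel never fits in a 3 s epoch minus one sample
  expect_warning(tfr_transform(es, tfr_spec(freqs = 1, times = 0),
                               channels = "POz"), "invalid|fits")
})

test_that("prestimulus purity: the alpha window at -250 ms ends before onset", {
  es <- const_epochs(0)
  w <- make_tapered_wavelet(10, fs = 250)
  half <- (length(w) - 1) / 2
  t_ms <- std_times()
  center_idx <- which.min(abs(t_ms + 250))
  window_times <- t_ms[(center_idx - half):(center_idx + half)]
  expect_true(all(window_times < 0))
})

test_that("DC input sits near the log-power floor at alpha frequencies", {
  es <- const_epochs(1)
  lp <- log_power(tfr_transform(es, tfr_spec(freqs = c(8, 10, 12), times = 0),
                                channels = "POz"))
  expect_true(all(lp < -15))    # taper sidelobe leakage only
})

test_that("zero signals flag undefined phase instead of silently reporting 0", {
  es <- const_epochs(0)
  tf <- tfr_transform(es, tfr_spec(freqs = 10, times = 0), channels = "POz")
  expect_warning(ph <- phase_angles(tf), "undefined")
  expect_true(all(is.na(ph)))
})
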