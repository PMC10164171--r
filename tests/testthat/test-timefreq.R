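test_that("zero signal decomposes to zero power", {
  times <- seq(-1, 1, by = 1 / 128)
  x <- array(0, c(2, 3, length(times)))
  tfr <- morlet_tfr(x, c(4, 8), times = times, sfreq = 128)
  expect_true(all(tfr$power == 0 | is.na(tfr$power)))
  expect_true(anyNA(tfr$power))              # edges are marked invalid
})

test_that("FFT decomposition matches direct time-domain convolution", {
  # independent oracle: stats::convolve with the same wavelet
  sfreq <- 128
  times <- seq(-1.5, 1.5 - 1 / sfreq, by = 1 / sfreq)
  set.seed(11)
  x <- sin(2 * pi * 6 * times) + 0.3 * rnorm(length(times))
  arr <- array(x, c(1, 1, length(times)))
  tfr <- morlet_tfr(arr, c(6, 10), times = times, sfreq = sfreq)
  for (fi in 1:2) {
    wav <- morlet_wavelet(tfr$frequencies[fi], sfreq)
    direct <- Mod(stats::convolve(x, rev(Conj(wav)), type = "open"))^2
    h <- (length(wav) - 1) / 2
    direct <- direct[(h + 1):(h + length(x))]
    got <- tfr$power[1, 1, fi, ]
    ok <- !is.na(got)
    expect_equal(got[ok], direct[ok], tolerance = 1e-8)
  }
})

test_that("a 6 Hz sinusoid concentrates power at the matching wavelet", {
  sfreq <- 256
  times <- seq(-2, 2 - 1 / sfreq, by = 1 / sfreq)
  x <- array(sin(2 * pi * 6 * times), c(1, 1, length(times)))
  tfr <- morlet_tfr(x, c(6, 12), times = times, sfreq = sfreq)
  mid <- which.min(abs(tfr$times))
  ratio <- tfr$power[1, 1, 1, mid] / tfr$power[1, 1, 2, mid]
  # closed-form ratio from the Gaussian spectral profiles of unit-energy
  # 5-cycle wavelets: |W_6(6)|^2 / |W_12(6)|^2
  spec_peak <- function(fc, f) {
    sigma_t <- 5 / (2 * pi * fc)
    sqrt(sigma_t) * exp(-(2 * pi * (f - fc))^2 * sigma_t^2 / 2)
  }
  expected <- (spec_peak(6, 6) / spec_peak(12, 6))^2
  expect_gt(ratio, 50)
  expect_lt(abs(log(ratio / expected)), 0.25)
})

test_that("doubling the amplitude quadruples the power", {
  sfreq <- 128
  times <- seq(-1.5, 1.5 - 1 / sfreq, by = 1 / sfreq)
  mk <- function(a) array(a * sin(2 * pi * 8 * times),
                          c(1, 1, length(times)))
  p1 <- morlet_tfr(mk(1), 8, times = times, sfreq = sfreq)$power
  p2 <- morlet_tfr(mk(2), 8, times = times, sfreq = sfreq)$power
  ok <- !is.na(p1)
  expect_equal(p2[ok], 4 * p1[ok], tolerance = 1e-10)
})

test_that("frequencies at or above Nyquist are rejected", {
  times <- seq(0, 2, by = 1 / 64)
  x <- array(0, c(1, 1, length(times)))
  expect_error(morlet_tfr(x, c(4, 32), times = times, sfreq = 64),
               "Nyquist")
})

test_that("the 2-15 Hz source grid has 27 bins and band averaging is inclusive", {
  freqs <- seq(2, 15, by = 0.5)
  expect_length(freqs, 27)
  sfreq <- 64
  times <- seq(-3, 3 - 1 / sfreq, by = 1 / sfreq)
  set.seed(3)
  x <- array(rnorm(2 * 2 * length(times)), c(2, 2, length(times)))
  tfr <- morlet_tfr(x, freqs, times = times, sfreq = sfreq)
  theta <- band_power(tfr, c(4, 7))
  sel <- which(freqs >= 4 & freqs <= 7)
  expect_length(sel, 7)
  manual <- apply(tfr$power[, , sel, , drop = FALSE], c(1, 2, 4), mean)
  expect_equal(theta$power, manual, tolerance = 1e-12)
  alpha <- band_power(tfr, c(8, 12))
  expect_length(which(freqs >= 8 & freqs <= 12), 9)
  single <- band_power(tfr, c(6, 6))
  expect_equal(single$power[1, 1, ], tfr$power[1, 1, which(freqs == 6), ],
               tolerance = 1e-12)
  expect_error(band_power(tfr, c(0.1, 0.2)), "no frequency bins")
})

test_that("condition averaging reduces the trial dimension by the mean", {
  times <- seq(0, 1, by = 0.1)
  p <- array(0, c(4, 2, length(times)))
  p[1, , ] <- 1; p[2, , ] <- 3                # overlap pair: mean 2
  p[3, , ] <- 5; p[4, , ] <- 5
  co <- band_power_course(p, times, c(4, 7))
  labs <- c("nogo_overlap", "nogo_overlap", "nogo_nonoverlap",
            "nogo_nonoverlap")
  ov <- condition_average(co, labs, "nogo_overlap")
  expect_equal(dim(ov$power), c(1, 2, length(times)))
  expect_true(all(ov$power == 2))
  expect_equal(ov$n_trials_averaged, 2)
  expect_error(condition_average(co, labs, "go_overlap"), "no trials")
})

test_that("peak latency finds the largest local maximum", {
  times <- seq(0, 1.2, by = 1 / 256)
  bump <- exp(-(times - 0.52)^2 / (2 * 0.05^2))
  pk <- peak_latency(bump, times, c(0, 1))
  expect_equal(pk$time, 0.52, tolerance = 1 / 256)
  expect_false(pk$boundary)

  two <- exp(-(times - 0.3)^2 / (2 * 0.03^2)) +
    2 * exp(-(times - 0.7)^2 / (2 * 0.03^2))
  expect_equal(peak_latency(two, times, c(0, 1))$time, 0.7,
               tolerance = 1 / 128)

  mono <- peak_latency(times, times, c(0, 1))
  expect_equal(mono$time, 1.0, tolerance = 1 / 256)
  expect_true(mono$boundary)

  flat <- peak_latency(rep(1, length(times)), times, c(0, 1))
  expect_true(flat$degenerate)
})
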