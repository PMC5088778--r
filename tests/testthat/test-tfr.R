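# epochs holding arbitrary signals (replicated over an 8-sensor layout so
# every channel has the same, analyzable content)
signal_epochs <- function(signals, srate = 256, t0 = -1) {
  # signals: list of numeric vectors (one per trial), equal length
  n <- length(signals[[1]])
  lay <- build_layout(8)
  arr <- array(0, c(length(signals), nrow(lay$channels), n))
  for (i in seq_along(signals)) {
    arr[i, , ] <- matrix(signals[[i]], nrow(lay$channels), n, byrow = TRUE)
  }
  times <- t0 + (seq_len(n) - 1) / srate
  trials <- tibble::tibble(trial = seq_along(signals))
  eeg_epochs(arr, times, srate, lay, trials)
}

test_that("a pure 10 Hz tone peaks at 10 Hz at every interior timepoint", {
  srate <- 256
  tt <- seq(0, 4 - 1 / srate, by = 1 / srate)
  ep <- signal_epochs(list(sin(2 * pi * 10 * tt)), srate, t0 = 0)
  pw <- compute_power(ep, tfr_config(freqs = 4:20))
  interior <- which(!is.na(pw$values[1, 1, 1, ])) # lowest freq defines edges
  expect_gt(length(interior), 20)
  peak <- apply(pw$values[1, 1, , interior], 2, which.max)
  expect_true(all(pw$freqs[peak] == 10))
  # unit amplitude -> power ~1 at 10 Hz
  expect_equal(unname(pw$values[1, 1, pw$freqs == 10, interior[5]]), 1,
               tolerance = 1e-3)
})

test_that("zero signal gives identically zero power", {
  ep <- signal_epochs(list(numeric(512)), srate = 256, t0 = 0)
  pw <- compute_power(ep, tfr_config(freqs = c(5, 10)))
  vals <- pw$values[1, 1, , ]
  expect_true(all(vals[!is.na(vals)] == 0))
})

test_that("interior power matches the direct Hann-DFT oracle to 1e-8", {
  srate <- 256
  tt <- seq(0, 3 - 1 / srate, by = 1 / srate)
  set.seed(8)
  sig <- sin(2 * pi * 10 * tt + 0.7) + 0.3 * sin(2 * pi * 6 * tt) +
    rnorm(length(tt), sd = 0.1)
  ep <- signal_epochs(list(sig), srate, t0 = 0)
  cfg <- tfr_config(freqs = c(6, 10, 13))
  pw <- compute_power(ep, cfg)
  for (f_i in seq_along(cfg$freqs)) {
    for (t_i in seq_along(pw$times)) {
      got <- pw$values[1, 1, f_i, t_i]
      want <- oracle_tfr_power(sig, srate, cfg$freqs[f_i], pw$times[t_i],
                               ep$times)
      if (is.na(want)) expect_true(is.na(got)) else
        expect_equal(got, want, tolerance = 1e-8)
    }
  }
})

test_that("power is quadratic in signal amplitude", {
  srate <- 256
  tt <- seq(0, 2 - 1 / srate, by = 1 / srate)
  sig <- sin(2 * pi * 10 * tt) + 0.2 * cos(2 * pi * 17 * tt)
  for (a in c(0.5, 3)) {
    p1 <- compute_power(signal_epochs(list(sig), srate, 0),
                        tfr_config(freqs = 8:12))
    pa <- compute_power(signal_epochs(list(a * sig), srate, 0),
                        tfr_config(freqs = 8:12))
    ratio <- pa$values / p1$values
    ratio <- ratio[is.finite(ratio)]
    expect_equal(ratio, rep(a^2, length(ratio)), tolerance = 1e-8)
  }
})

test_that("time-shift covariance: a shifted burst shifts its power ridge", {
  srate <- 256
  n <- 768
  burst <- function(center_s) {
    tt <- (seq_len(n) - 1) / srate
    env <- exp(-((tt - center_s) / 0.1)^2)
    env * sin(2 * pi * 10 * tt)
  }
  cfg <- tfr_config(freqs = 10, time_step = 1 / 256)
  p1 <- compute_power(signal_epochs(list(burst(1.0)), srate, 0), cfg)
  p2 <- compute_power(signal_epochs(list(burst(1.25)), srate, 0), cfg)
  peak1 <- p1$times[which.max(p1$values[1, 1, 1, ])]
  peak2 <- p2$times[which.max(p2$values[1, 1, 1, ])]
  expect_equal(peak2 - peak1, 0.25, tolerance = 2 / srate)
})

test_that("frequencies whose window exceeds the epoch are fully masked", {
  ep <- signal_epochs(list(rnorm(256)), srate = 256, t0 = 0) # 1 s epoch
  expect_warning(pw <- compute_power(ep, tfr_config(freqs = c(2, 10))),
                 "masked")
  expect_true(all(is.na(pw$values[1, 1, 1, ]))) # 3 cycles at 2 Hz = 1.5 s
  expect_false(all(is.na(pw$values[1, 1, 2, ])))
})

test_that("stationary noise has relative power centered on zero", {
  set.seed(21)
  sigs <- lapply(1:60, function(i) rnorm(1101))
  ep <- signal_epochs(sigs, srate = 256, t0 = -2.4)
  pw <- compute_power(ep, tfr_config(freqs = 10))
  rel <- baseline_relative(pw, c(-2.2, -1.8))
  post <- rel$values[, 1, 1, rel$times > 0 & rel$times <= 1.7]
  m <- mean(post)
  se <- sd(rowMeans(post)) / sqrt(nrow(post))
  expect_lt(abs(m), 3 * se)
})

test_that("a power step after t = 0 maps to the exact relative change", {
  # raw power doubling after t=0 -> relative change 1.0 in the post window
  srate <- 256
  tt <- seq(-2, 2 - 1 / srate, by = 1 / srate)
  amp <- ifelse(tt < 0, 1, sqrt(2)) # power = amp^2
  sig <- amp * sin(2 * pi * 10 * tt)
  ep <- signal_epochs(list(sig), srate, t0 = -2)
  pw <- compute_power(ep, tfr_config(freqs = 10))
  rel <- baseline_relative(pw, c(-1.5, -1.0))
  post <- rel$values[1, 1, 1, rel$times > 0.3 & rel$times < 1.5]
  expect_equal(mean(post), 1.0, tolerance = 0.02)
})

test_that("band averaging is the unweighted mean over in-band frequencies", {
  vals <- array(0, c(1, 1, 5, 3))
  vals[1, 1, , ] <- matrix(1:15, 5, 3)
  pm <- power_map(vals, freqs = 8:12, times = c(0, 0.05, 0.1),
                  channels = "O1")
  ba <- band_average(pm, c(8, 12))
  expect_equal(ba$values[1, 1, 1, ], colMeans(matrix(1:15, 5, 3)))
  one <- band_average(pm, c(9, 9))
  expect_equal(one$values[1, 1, 1, ], vals[1, 1, 2, ])
  expect_error(band_average(pm, c(20, 25)), "no grid frequencies")
})

test_that("baseline errors are explicit", {
  vals <- array(1, c(2, 1, 1, 4))
  pm <- power_map(vals, 10, c(-0.2, -0.1, 0, 0.1), "O1")
  expect_error(baseline_relative(pm, c(5, 6)), "no timepoints")
  rel <- baseline_relative(pm, c(-0.2, -0.1))
  expect_error(baseline_relative(rel, c(-0.2, -0.1)), "already")
  pm0 <- power_map(array(0, c(2, 1, 1, 4)), 10, c(-0.2, -0.1, 0, 0.1), "O1")
  expect_error(baseline_relative(pm0, c(-0.2, -0.1)), "zero baseline")
})
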