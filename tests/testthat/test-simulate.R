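test_that("simulation is byte-identical under a fixed seed", {
  p <- tiny_params()
  lay <- build_layout(p$n_channels)
  c1 <- simulate_cohort(p, seed = 99, layout = lay)
  c2 <- simulate_cohort(p, seed = 99, layout = lay)
  expect_identical(c1, c2)
  expect_length(c1, 3)
  expect_identical(vapply(c1, function(s) s$epochs$subject_id, ""),
                   c("S01", "S02", "S03"))
})

test_that("zero jitter gives identical effect magnitudes across subjects", {
  p <- sim_params(n_subjects = 4, subject_jitter_sd = 0, coupling_alpha = 0)
  plan <- cohort_plan(p, seed = 3)
  effs <- lapply(seq_len(4), function(i) {
    alphalat:::subject_effects(p, plan[i, ])
  })
  for (i in 2:4) {
    expect_equal(effs[[i]]$alpha_effects$asymmetry,
                 effs[[1]]$alpha_effects$asymmetry)
    expect_equal(effs[[i]]$theta_amp, effs[[1]]$theta_amp)
  }
})

test_that("injected alpha raises posterior 8-12 Hz spectral power", {
  p <- sim_params(trials_per_condition = 7, n_channels = 16) # 56 trials
  lay <- build_layout(16)
  sched <- generate_schedule(p, seed = 1)[1:50, ]
  ep_alpha <- simulate_subject(sched, lay, p, seed = 2)
  p0 <- p; p0$alpha_amp <- 0
  ep_null <- simulate_subject(sched, lay, p0, seed = 2)

  band_power <- function(ep, ch) {
    vapply(seq_len(dim(ep$data)[1]), function(tr) {
      sp <- stats::spec.pgram(ts(ep$data[tr, ch, ], frequency = ep$srate),
                              plot = FALSE, taper = 0.1, detrend = TRUE)
      mean(sp$spec[sp$freq >= 8 & sp$freq <= 12])
    }, numeric(1))
  }
  o1 <- match("O1", lay$channels$name)
  bp_alpha <- band_power(ep_alpha, o1)
  bp_null <- band_power(ep_null, o1)
  tt <- t.test(bp_alpha, bp_null, alternative = "greater")
  expect_lt(tt$p.value, 0.01)

  # posterior sensors carry more alpha than frontal sensors
  fz <- match("Fz", lay$channels$name)
  expect_gt(mean(bp_alpha), mean(band_power(ep_alpha, fz)))
})

test_that("cued left-target trials have lower contralateral pretarget alpha", {
  p <- sim_params(trials_per_condition = 20, n_channels = 16)
  lay <- build_layout(16)
  sched <- generate_schedule(p, seed = 4)
  sched <- sched[sched$cue_presence == "cued" & sched$target_side == "left", ]
  ep <- simulate_subject(sched, lay, p, seed = 5)
  # direct band power in the injected window, independent of the TFR module
  sel <- ep$times >= -1.05 & ep$times <= 0
  band_power <- function(ch) {
    vapply(seq_len(dim(ep$data)[1]), function(tr) {
      x <- ep$data[tr, ch, sel]
      sp <- Mod(fft(x * hanning_vec(length(x))))^2
      fr <- (seq_along(x) - 1) * ep$srate / length(x)
      mean(sp[fr >= 8 & fr <= 12])
    }, numeric(1))
  }
  hanning_vec <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  left_post <- match(c("O1", "PO7"), lay$channels$name)
  right_post <- match(c("O2", "PO8"), lay$channels$name)
  # left target: right hemisphere is contralateral and should be lower
  ipsi <- rowMeans(cbind(band_power(left_post[1]), band_power(left_post[2])))
  contra <- rowMeans(cbind(band_power(right_post[1]), band_power(right_post[2])))
  expect_lt(t.test(contra, ipsi, paired = TRUE,
                   alternative = "less")$p.value, 0.01)
})

test_that("theta bursts appear only on uncued high-similarity trials", {
  p <- sim_params(trials_per_condition = 12, n_channels = 16, alpha_amp = 0,
                  theta_amp = 2)
  lay <- build_layout(16)
  sched <- generate_schedule(p, seed = 6)
  ep <- simulate_subject(sched, lay, p, seed = 7)
  sel <- ep$times >= 0.7 & ep$times <= 1.25
  fcz <- match("FCz", lay$channels$name)
  var_in_win <- apply(ep$data[, fcz, sel], 1, var)
  on <- sched$cue_presence == "uncued" & sched$distractor %in% c("D1", "D2")
  expect_gt(mean(var_in_win[on]), 1.5 * mean(var_in_win[!on]))
})

test_that("effect windows outside the epoch are rejected", {
  p <- tiny_params()
  bad <- p$alpha_effects
  bad$start[1] <- -5
  lay <- build_layout(16)
  sched <- generate_schedule(p, seed = 1)
  expect_error(simulate_subject(sched, lay, p, alpha_effects = bad),
               "outside the epoch")
  expect_error(sim_params(theta_window = c(1.5, 3)), "epoch")
})

test_that("epochs container enforces its invariants", {
  p <- tiny_params()
  lay <- build_layout(16)
  ep <- simulate_subject(generate_schedule(p, 1), lay, p, seed = 2)
  expect_true(all(is.finite(ep$data)))
  expect_identical(length(ep$times), dim(ep$data)[3])
  expect_equal(diff(ep$times), rep(1 / p$srate, length(ep$times) - 1))
  bad <- ep$data; bad[1] <- NA
  expect_error(eeg_epochs(bad, ep$times, ep$srate, lay, ep$trials), "finite")
  expect_error(eeg_epochs(ep$data, ep$times[-1], ep$srate, lay, ep$trials),
               "times")
})
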