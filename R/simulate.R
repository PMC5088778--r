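#' Simulate one subject's epoched oscillatory EEG
#'
#' Generates a trials x channels x samples array holding, per trial:
#' \itemize{
#'   \item per-channel 1/f^beta background noise plus a rank-2 spatially
#'     shared noise component (so channels are correlated, as in real EEG);
#'   \item an ongoing alpha oscillation on the posterior channel group with
#'     random uniform phase per trial and channel (induced, not
#'     phase-locked: power survives per-trial time-frequency analysis while
#'     the evoked average tends to zero), whose amplitude is scaled by
#'     `1 + a` ipsilateral and `1 - a` contralateral to the target inside
#'     the trial's condition-specific effect window(s), with raised-cosine
#'     on/off ramps;
#'   \item a midfrontal theta burst (700-1250 ms post-target by default)
#'     on uncued high-similarity (D1/D2) trials only.
#' }
#'
#' @param schedule Trial tibble from [generate_schedule()] (behavior columns
#'   are carried along if present).
#' @param layout An [build_layout()] layout.
#' @param params A [sim_params()] object.
#' @param seed Optional integer seed.
#' @param subject_id Subject identifier.
#' @param alpha_effects Override for `params$alpha_effects` (used by
#'   [simulate_cohort()] to apply per-subject jitter).
#' @param theta_amp Override for `params$theta_amp`.
#' @return An [eeg_epochs()] object.
#' @examples
#' p <- sim_params(trials_per_condition = 6, n_channels = 16)
#' ep <- simulate_subject(generate_schedule(p, 1), build_layout(16), p, 2)
#' dim(ep$data)
#' @export
simulate_subject <- function(schedule, layout, params = sim_params(),
                             seed = NULL, subject_id = "S01",
                             alpha_effects = NULL, theta_amp = NULL) {
  alpha_effects <- alpha_effects %||% params$alpha_effects
  theta_amp <- theta_amp %||% params$theta_amp
  check_windows_in_epoch(alpha_effects, params)

  times <- epoch_times(params$epoch_window, params$srate)
  n_samp <- length(times)
  n_ch <- nrow(layout$channels)
  n_trials <- nrow(schedule)

  hemi <- layout$channels$hemisphere
  post_idx <- match(layout$posterior, layout$channels$name)
  mid_idx <- match(layout$midfrontal, layout$channels$name)

  # per-condition asymmetry envelope a_eff(t)
  sim_lvl <- ifelse(schedule$distractor %in% c("D1", "D2"), "high", "low")
  cond_key <- paste(schedule$cue_presence, sim_lvl, sep = ".")
  aeff <- condition_asymmetry_envelopes(alpha_effects, times, params$ramp)
  theta_env <- theta_amp * raised_cosine_env(
    times, params$theta_window[1], params$theta_window[2], params$ramp
  )
  theta_on <- schedule$cue_presence == "uncued" & sim_lvl == "high"

  # hemisphere sign per posterior channel: +1 ipsi, -1 contra, 0 midline
  hemi_sign <- function(target_side) {
    s <- ifelse(hemi[post_idx] == "M", 0,
                ifelse((hemi[post_idx] == "L") == (target_side == "left"),
                       1, -1))
    s
  }

  out <- with_seed(seed, {
    arr <- array(0, dim = c(n_samp, n_ch, n_trials))

    # background noise, chunked over trials to bound memory
    chunk <- max(1L, 2000000L %/% (n_samp * n_ch))
    starts <- seq(1L, n_trials, by = chunk)
    for (s0 in starts) {
      tr <- s0:min(s0 + chunk - 1L, n_trials)
      noise <- pink_noise(n_samp, n_ch * length(tr), params$noise_exponent,
                          params$noise_sd)
      arr[, , tr] <- noise
    }

    # rank-2 spatially shared component
    if (params$shared_noise_sd > 0) {
      u <- matrix(stats::rnorm(n_ch * 2), n_ch, 2)
      u <- sweep(u, 2, sqrt(colSums(u^2)), "/")
      for (s0 in starts) {
        tr <- s0:min(s0 + chunk - 1L, n_trials)
        ts_noise <- pink_noise(n_samp, 2L * length(tr),
                               params$noise_exponent,
                               params$shared_noise_sd)
        dim(ts_noise) <- c(n_samp, 2L, length(tr))
        for (j in seq_along(tr)) {
          arr[, , tr[j]] <- arr[, , tr[j]] + ts_noise[, , j] %*% t(u)
        }
      }
    }

    two_pi <- 2 * pi
    for (i in seq_len(n_trials)) {
      # posterior alpha with lateralized amplitude modulation
      if (length(post_idx) > 0 && params$alpha_amp > 0) {
        phase <- stats::runif(length(post_idx), 0, two_pi)
        carrier <- sin(outer(times, rep(two_pi * params$alpha_freq,
                                        length(post_idx))) +
                         matrix(phase, n_samp, length(post_idx), byrow = TRUE))
        amp <- params$alpha_amp *
          (1 + outer(aeff[[cond_key[i]]],
                     hemi_sign(schedule$target_side[i])))
        arr[, post_idx, i] <- arr[, post_idx, i] + amp * carrier
      }
      # midfrontal theta burst, uncued high-similarity trials only
      if (theta_on[i] && length(mid_idx) > 0 && theta_amp > 0) {
        phase <- stats::runif(length(mid_idx), 0, two_pi)
        carrier <- sin(outer(times, rep(two_pi * params$theta_freq,
                                        length(mid_idx))) +
                         matrix(phase, n_samp, length(mid_idx), byrow = TRUE))
        arr[, mid_idx, i] <- arr[, mid_idx, i] + theta_env * carrier
      }
    }
    arr
  })

  eeg_epochs(
    data = aperm(out, c(3, 2, 1)), times = times, srate = params$srate,
    layout = layout, trials = schedule, subject_id = subject_id
  )
}

#' Per-subject randomization plan for a cohort
#'
#' Derives, from one cohort seed, the per-subject child seeds, the latent
#' distraction-susceptibility trait `z` (standard normal) and the log-normal
#' between-subject effect multipliers. [simulate_cohort()] and the pipeline
#' both consume this plan, so a cohort can be generated subject-by-subject
#' without holding all subjects in memory while staying byte-identical to
#' `simulate_cohort()` under the same seed.
#'
#' @param params A [sim_params()] object.
#' @param seed Cohort seed.
#' @return Tibble with one row per subject: `subject_id`, `seed_schedule`,
#'   `seed_behavior`, `seed_eeg`, `z`, `jitter_alpha`, `jitter_theta`.
#' @export
cohort_plan <- function(params = sim_params(), seed = NULL) {
  n <- params$n_subjects
  with_seed(seed, {
    z <- stats::rnorm(n)
    j_alpha <- exp(stats::rnorm(n, 0, params$subject_jitter_sd))
    j_theta <- exp(stats::rnorm(n, 0, params$subject_jitter_sd))
    seeds <- sample.int(.Machine$integer.max %/% 2L, 3L * n)
    tibble::tibble(
      subject_id = sprintf("S%02d", seq_len(n)),
      seed_schedule = seeds[seq_len(n)],
      seed_behavior = seeds[n + seq_len(n)],
      seed_eeg = seeds[2L * n + seq_len(n)],
      z = z, jitter_alpha = j_alpha, jitter_theta = j_theta
    )
  })
}

# Effect parameters for one row of a cohort plan: jittered alpha asymmetries
# (with the uncued/low asymmetry additionally coupled to z), jittered theta
# amplitude, and the RT shift applied to the uncued D1/D2 cells.
subject_effects <- function(params, plan_row) {
  eff <- params$alpha_effects
  eff$asymmetry <- eff$asymmetry * plan_row$jitter_alpha
  low_uncued <- eff$cue_presence == "uncued" & eff$similarity == "low"
  eff$asymmetry[low_uncued] <- eff$asymmetry[low_uncued] *
    exp(params$coupling_alpha * plan_row$z)
  list(
    alpha_effects = eff,
    theta_amp = params$theta_amp * plan_row$jitter_theta,
    rt_shift = c(
      "uncued.D1" = params$coupling_rt * plan_row$z,
      "uncued.D2" = params$coupling_rt * plan_row$z
    )
  )
}

#' Simulate one subject of a cohort plan
#'
#' @param params A [sim_params()] object.
#' @param layout Layout shared by the cohort.
#' @param plan_row One row of [cohort_plan()].
#' @return List with `epochs` (an [eeg_epochs()] whose trial table includes
#'   the behavior columns) and `behavior` (the trial/behavior tibble).
#' @export
simulate_cohort_subject <- function(params, layout, plan_row) {
  eff <- subject_effects(params, plan_row)
  schedule <- generate_schedule(params, plan_row$seed_schedule)
  behavior <- simulate_behavior(schedule, params, plan_row$seed_behavior,
                                rt_shift_ms = eff$rt_shift)
  epochs <- simulate_subject(
    schedule = behavior, layout = layout, params = params,
    seed = plan_row$seed_eeg, subject_id = plan_row$subject_id,
    alpha_effects = eff$alpha_effects, theta_amp = eff$theta_amp
  )
  list(epochs = epochs, behavior = behavior)
}

#' Simulate a cohort of subjects
#'
#' Generates `params$n_subjects` independent subjects with per-subject
#' log-normal jitter on effect sizes and a latent trait coupling each
#' subject's distractor cost to their uncued/low alpha lateralization (see
#' [sim_params()]). Deterministic under a fixed seed.
#'
#' @inheritParams cohort_plan
#' @param layout Optional layout; default `build_layout(params$n_channels)`.
#' @return List of length `n_subjects`; each element is a list with
#'   `epochs` and `behavior` (see [simulate_cohort_subject()]).
#' @export
simulate_cohort <- function(params = sim_params(), seed = NULL,
                            layout = NULL) {
  layout <- layout %||% build_layout(params$n_channels)
  plan <- cohort_plan(params, seed)
  lapply(seq_len(nrow(plan)), function(i) {
    simulate_cohort_subject(params, layout, plan[i, ])
  })
}

check_windows_in_epoch <- function(alpha_effects, params) {
  ep <- params$epoch_window
  bad <- alpha_effects$start < ep[1] | alpha_effects$end > ep[2]
  if (any(bad)) stop("alpha effect window outside the epoch")
  if (params$theta_window[1] < ep[1] || params$theta_window[2] > ep[2]) {
    stop("theta window outside the epoch")
  }
}

# 1/f^beta noise, one column per independent series. FFT amplitude shaping
# of white noise; the analytic Parseval scale gives E[var] = sd^2 exactly.
# The FFT runs at the next 5-smooth length >= n (large prime lengths are
# slow) and the series is truncated back to n samples.
pink_noise <- function(n, n_cols, beta, sd = 1) {
  white <- matrix(stats::rnorm(n * n_cols), n, n_cols)
  if (beta == 0) return(sd * white)
  n_fft <- stats::nextn(n, c(2, 3, 5))
  if (n_fft > n) {
    white <- rbind(white, matrix(stats::rnorm((n_fft - n) * n_cols),
                                 n_fft - n, n_cols))
  }
  k <- seq_len(n_fft) - 1
  f_fold <- pmin(k, n_fft - k) # frequency index folded at Nyquist
  g <- c(0, f_fold[-1]^(-beta / 2))
  spec <- stats::mvfft(white) * g
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n_fft
  x[seq_len(n), , drop = FALSE] * (sd / sqrt(mean(g^2)))
}

# Raised-cosine window envelope: 0 outside [start, end], ramps of length
# `ramp` (shrunk to half the window if the window is short), 1 in between.
raised_cosine_env <- function(times, start, end, ramp) {
  r <- min(ramp, (end - start) / 2)
  env <- numeric(length(times))
  inside <- times >= start & times <= end
  env[inside] <- 1
  if (r > 0) {
    up <- times >= start & times < start + r
    env[up] <- 0.5 * (1 - cos(pi * (times[up] - start) / r))
    down <- times > end - r & times <= end
    env[down] <- 0.5 * (1 - cos(pi * (end - times[down]) / r))
  }
  env
}

# Sum of asymmetry-weighted envelopes per cue x similarity condition.
condition_asymmetry_envelopes <- function(alpha_effects, times, ramp) {
  conds <- expand.grid(cue = c("cued", "uncued"), sim = c("high", "low"),
                       stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(conds))) {
    rows <- alpha_effects[
      alpha_effects$cue_presence == conds$cue[i] &
        alpha_effects$similarity %in% c("any", conds$sim[i]), , drop = FALSE]
    env <- numeric(length(times))
    if (nrow(rows)) {
      for (j in seq_len(nrow(rows))) {
        env <- env + rows$asymmetry[j] *
          raised_cosine_env(times, rows$start[j], rows$end[j], ramp)
      }
    }
    out[[paste(conds$cue[i], conds$sim[i], sep = ".")]] <- env
  }
  out
}
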