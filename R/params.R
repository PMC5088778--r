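#' Simulation parameters for a synthetic cued visual-search EEG cohort
#'
#' Bundles every tunable of the synthetic-cohort generator: the factorial
#' design (2 cue-presence x 4 distractor-similarity levels, balanced target
#' sides and letters), the behavioral model (per-cell reaction-time and
#' accuracy parameters), and the oscillatory signal model (ongoing posterior
#' alpha with condition-specific lateralization windows, a midfrontal theta
#' burst confined to uncued high-similarity trials, 1/f background noise).
#'
#' Default reaction-time cell means reconstruct the 2 x 4 table from the
#' marginal per-distractor means (D1 910.2, D2 875.2, D3 803.6, D4 798.8 ms)
#' and the cue benefits (D1 159.8, D2 126.3, D3 51.5, D4 46.9 ms):
#' `cued = mean - benefit/2`, `uncued = mean + benefit/2`. Default accuracy
#' cells average to 0.879 with a small similarity effect that is larger on
#' uncued trials.
#'
#' Alpha lateralization (amplitude lower contralateral to the target) is
#' injected in condition-specific windows: cued trials in -1050..0 ms
#' pretarget; cued/low-similarity 350..500 ms post-target; cued/high 0..150
#' and 450..750 ms; uncued/low 500..900 ms; uncued/high none. The theta
#' burst spans 700..1250 ms post-target on midfrontal sensors, uncued
#' high-similarity trials only.
#'
#' @param n_subjects Number of simulated participants (default 16).
#' @param trials_per_condition Trials per cue-presence x distractor cell
#'   (default 108, i.e. 864 trials total).
#' @param n_channels Layout size passed to [build_layout()].
#' @param srate Sampling rate, Hz.
#' @param epoch_window Epoch limits in seconds relative to target onset.
#' @param alpha_freq,theta_freq Oscillation frequencies, Hz.
#' @param alpha_amp Ongoing posterior alpha amplitude (signal units; the
#'   1/f noise has unit RMS).
#' @param theta_amp Midfrontal theta burst amplitude for uncued
#'   high-similarity trials.
#' @param alpha_asymmetry Relative amplitude asymmetry `a`: inside an effect
#'   window the alpha amplitude is scaled by `1 + a` ipsilateral and
#'   `1 - a` contralateral to the target.
#' @param alpha_effects Data frame of effect windows with columns
#'   `cue_presence` ("cued"/"uncued"), `similarity` ("high"/"low"/"any"),
#'   `start`, `end` (s) and `asymmetry`. `NULL` uses the defaults above
#'   with `alpha_asymmetry`.
#' @param theta_window Two-element window (s) of the theta burst.
#' @param noise_exponent Spectral slope beta of the 1/f^beta background.
#' @param noise_sd RMS of the per-channel background noise.
#' @param shared_noise_sd RMS of a rank-2 spatially shared noise component.
#' @param ramp Raised-cosine on/off ramp length (s) for effect envelopes.
#' @param rt_model Data frame with `cue_presence`, `distractor`, `mean_ms`,
#'   `sd_ms`; `NULL` uses the reconstructed default table with `rt_sd_ms`.
#' @param rt_sd_ms Within-cell trial-to-trial RT standard deviation, ms.
#' @param accuracy_model Data frame with `cue_presence`, `distractor`,
#'   `p_correct`; `NULL` uses the defaults.
#' @param eye_move_rate Probability a trial is flagged as an eye movement
#'   (condition-independent metadata; no ocular signal is simulated).
#' @param subject_jitter_sd SD of the log-normal between-subject multiplier
#'   applied to alpha asymmetries and theta amplitude.
#' @param coupling_rt RT coupling (ms per SD) of the latent
#'   distraction-susceptibility trait: added to the uncued D1/D2 cell means.
#' @param coupling_alpha Log-scale coupling of the same trait to the
#'   uncued/low alpha asymmetry (multiplier `exp(coupling_alpha * z)`).
#'   Together with `coupling_rt` this induces the negative correlation
#'   between distractor cost and the high-minus-low lateralization
#'   difference; set both to 0 to decouple brain and behavior.
#' @return A validated list of class `sim_params`.
#' @examples
#' p <- sim_params(n_subjects = 4, trials_per_condition = 12, n_channels = 16)
#' p$rt_model
#' @export
sim_params <- function(n_subjects = 16,
                       trials_per_condition = 108,
                       n_channels = 32,
                       srate = 256,
                       epoch_window = c(-2.4, 1.9),
                       alpha_freq = 10,
                       theta_freq = 5,
                       alpha_amp = 1.2,
                       theta_amp = 0.9,
                       alpha_asymmetry = 0.25,
                       alpha_effects = NULL,
                       theta_window = c(0.7, 1.25),
                       noise_exponent = 1.0,
                       noise_sd = 1.0,
                       shared_noise_sd = 0.4,
                       ramp = 0.1,
                       rt_model = NULL,
                       rt_sd_ms = 200,
                       accuracy_model = NULL,
                       eye_move_rate = 0.071,
                       subject_jitter_sd = 0.2,
                       coupling_rt = 40,
                       coupling_alpha = 0.4) {
  if (is.null(rt_model)) rt_model <- default_rt_model(rt_sd_ms)
  if (is.null(accuracy_model)) accuracy_model <- default_accuracy_model()
  if (is.null(alpha_effects)) alpha_effects <- default_alpha_effects(alpha_asymmetry)

  p <- list(
    n_subjects = as.integer(n_subjects),
    trials_per_condition = as.integer(trials_per_condition),
    n_channels = as.integer(n_channels),
    srate = srate,
    epoch_window = as.numeric(epoch_window),
    alpha_freq = alpha_freq,
    theta_freq = theta_freq,
    alpha_amp = alpha_amp,
    theta_amp = theta_amp,
    alpha_effects = tibble::as_tibble(alpha_effects),
    theta_window = as.numeric(theta_window),
    noise_exponent = noise_exponent,
    noise_sd = noise_sd,
    shared_noise_sd = shared_noise_sd,
    ramp = ramp,
    rt_model = tibble::as_tibble(rt_model),
    rt_sd_ms = rt_sd_ms,
    accuracy_model = tibble::as_tibble(accuracy_model),
    eye_move_rate = eye_move_rate,
    subject_jitter_sd = subject_jitter_sd,
    coupling_rt = coupling_rt,
    coupling_alpha = coupling_alpha
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(
    p$n_subjects >= 1,
    p$trials_per_condition >= 1,
    p$srate > 0,
    length(p$epoch_window) == 2,
    p$epoch_window[1] < p$epoch_window[2]
  )
  if (p$eye_move_rate < 0 || p$eye_move_rate > 1) {
    stop("`eye_move_rate` must be in [0, 1]")
  }
  if (any(p$accuracy_model$p_correct < 0 | p$accuracy_model$p_correct > 1)) {
    stop("accuracy probabilities must be in [0, 1]")
  }
  if (any(p$rt_model$mean_ms <= 0) || any(p$rt_model$sd_ms <= 0)) {
    stop("reaction-time means and SDs must be positive")
  }
  if (any(p$alpha_effects$asymmetry < 0)) {
    stop("alpha asymmetries must be >= 0 (sign convention: alpha is lower ",
         "contralateral to the target)")
  }
  win <- rbind(
    cbind(p$alpha_effects$start, p$alpha_effects$end),
    matrix(p$theta_window, ncol = 2)
  )
  if (any(win[, 1] >= win[, 2])) stop("effect windows must have start < end")
  if (any(win[, 1] < p$epoch_window[1]) || any(win[, 2] > p$epoch_window[2])) {
    stop("effect windows must lie inside the epoch window")
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> ", x$n_subjects, " subjects, ",
      8 * x$trials_per_condition, " trials each (",
      x$trials_per_condition, "/cell), ", x$n_channels, " channels @ ",
      x$srate, " Hz, epoch [", x$epoch_window[1], ", ", x$epoch_window[2],
      "] s\n", sep = "")
  cat("alpha ", x$alpha_freq, " Hz (amp ", x$alpha_amp, "), theta ",
      x$theta_freq, " Hz (amp ", x$theta_amp, "), noise 1/f^",
      x$noise_exponent, "\n", sep = "")
  invisible(x)
}

#' Default behavioral and oscillatory model tables
#'
#' `default_rt_model()` reconstructs the 8-cell reaction-time table from the
#' per-distractor marginal means and the per-distractor cue benefits;
#' `default_accuracy_model()` gives per-cell correct probabilities averaging
#' 0.879 with a cue-by-similarity interaction; `default_alpha_effects()`
#' lists the condition-specific lateralization windows.
#'
#' @param sd_ms Trial-level RT standard deviation applied to every cell.
#' @return A tibble (see [sim_params()] for column meanings).
#' @keywords internal
#' @export
default_rt_model <- function(sd_ms = 200) {
  d_mean <- c(D1 = 910.2, D2 = 875.2, D3 = 803.6, D4 = 798.8)
  benefit <- c(D1 = 159.8, D2 = 126.3, D3 = 51.5, D4 = 46.9)
  tibble::tibble(
    cue_presence = rep(c("cued", "uncued"), each = 4),
    distractor = rep(names(d_mean), 2),
    mean_ms = c(d_mean - benefit / 2, d_mean + benefit / 2),
    sd_ms = sd_ms
  )
}

#' @rdname default_rt_model
#' @export
default_accuracy_model <- function() {
  tibble::tibble(
    cue_presence = rep(c("cued", "uncued"), each = 4),
    distractor = rep(c("D1", "D2", "D3", "D4"), 2),
    p_correct = c(0.87, 0.88, 0.89, 0.89,
                  0.85, 0.87, 0.89, 0.89)
  )
}

#' @rdname default_rt_model
#' @param asymmetry Relative amplitude asymmetry applied in every window.
#' @export
default_alpha_effects <- function(asymmetry = 0.25) {
  tibble::tibble(
    cue_presence = c("cued", "cued", "cued", "cued", "uncued"),
    similarity   = c("any",  "low",  "high", "high", "low"),
    start        = c(-1.05,  0.35,   0.00,   0.45,   0.50),
    end          = c(0.00,   0.50,   0.15,   0.75,   0.90),
    asymmetry    = asymmetry
  )
}

#' Pool distractor-similarity levels
#'
#' Adds a `similarity` column pooling D1/D2 into `"high"` and D3/D4 into
#' `"low"`, the grouping used throughout the post-target analyses.
#'
#' @param trials Data frame with a `distractor` column (levels D1..D4).
#' @return The input as a tibble with a `similarity` column appended.
#' @examples
#' pool_similarity(data.frame(distractor = c("D1", "D4")))
#' @export
pool_similarity <- function(trials) {
  d <- trials$distractor
  if (is.null(d)) stop("`trials` must have a `distractor` column")
  bad <- setdiff(unique(as.character(d)), c("D1", "D2", "D3", "D4"))
  if (length(bad)) stop("unknown distractor level(s): ", toString(bad))
  dplyr::mutate(
    tibble::as_tibble(trials),
    similarity = ifelse(.data$distractor %in% c("D1", "D2"), "high", "low")
  )
}
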