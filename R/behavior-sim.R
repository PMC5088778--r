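#' Simulate behavioral outcomes for a trial schedule
#'
#' Draws a reaction time, a correctness flag and an eye-movement flag for
#' every trial. Reaction times come from a log-normal moment-matched to the
#' trial's cell mean and SD (so configured means/SDs are reproduced exactly
#' in expectation while RTs stay positive and right-skewed); correctness is
#' Bernoulli with the cell's correct probability; eye movements are
#' Bernoulli(`eye_move_rate`) independent of condition (metadata only, no
#' ocular signal is simulated).
#'
#' @param schedule Trial tibble from [generate_schedule()].
#' @param params A [sim_params()] object supplying `rt_model`,
#'   `accuracy_model` and `eye_move_rate`.
#' @param seed Optional integer seed.
#' @param rt_shift_ms Named numeric vector of per-cell mean shifts (names
#'   `"cued.D1"` etc.), used by the cohort generator to couple a subject's
#'   distraction susceptibility to behavior. Default no shift.
#' @return The schedule tibble with `rt_ms`, `correct` and `eye_movement`
#'   columns appended.
#' @examples
#' p <- sim_params(trials_per_condition = 12)
#' beh <- simulate_behavior(generate_schedule(p, seed = 1), p, seed = 2)
#' dplyr::summarise(dplyr::group_by(beh, cue_presence), rt = mean(rt_ms))
#' @export
simulate_behavior <- function(schedule, params = sim_params(), seed = NULL,
                              rt_shift_ms = NULL) {
  key <- paste(schedule$cue_presence, schedule$distractor, sep = ".")
  rt_key <- paste(params$rt_model$cue_presence, params$rt_model$distractor,
                  sep = ".")
  acc_key <- paste(params$accuracy_model$cue_presence,
                   params$accuracy_model$distractor, sep = ".")
  if (!all(key %in% rt_key)) stop("rt_model is missing cells: ",
                                  toString(setdiff(key, rt_key)))
  if (!all(key %in% acc_key)) stop("accuracy_model is missing cells: ",
                                   toString(setdiff(key, acc_key)))

  m <- params$rt_model$mean_ms[match(key, rt_key)]
  s <- params$rt_model$sd_ms[match(key, rt_key)]
  if (!is.null(rt_shift_ms)) {
    shift <- rt_shift_ms[key]
    shift[is.na(shift)] <- 0
    m <- m + as.numeric(shift)
  }
  if (any(m <= 0) || any(s <= 0)) {
    stop("reaction-time means and SDs must be positive")
  }
  p_corr <- params$accuracy_model$p_correct[match(key, acc_key)]

  # log-normal moment matching: E = m, SD = s
  sigma2 <- log(1 + s^2 / m^2)
  mu <- log(m) - sigma2 / 2

  with_seed(seed, {
    out <- tibble::as_tibble(schedule)
    out$rt_ms <- stats::rlnorm(nrow(out), meanlog = mu, sdlog = sqrt(sigma2))
    out$correct <- stats::runif(nrow(out)) < p_corr
    out$eye_movement <- stats::runif(nrow(out)) < params$eye_move_rate
    out
  })
}
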