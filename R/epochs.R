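#' Epoched EEG container
#'
#' Wraps a trials x channels x samples voltage array together with its time
#' axis, sampling rate, sensor layout and trial table. All downstream
#' time-frequency and statistical stages consume this container.
#'
#' @param data Numeric array, trials x channels x samples; all values must
#'   be finite.
#' @param times Numeric vector of sample times (s, relative to target
#'   onset), strictly increasing with spacing `1/srate`.
#' @param srate Sampling rate, Hz.
#' @param layout An [build_layout()] object whose channel count matches
#'   `dim(data)[2]`.
#' @param trials Trial tibble with one row per trial (schedule and,
#'   optionally, behavior columns).
#' @param subject_id Subject identifier string.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times, srate, layout, trials,
                       subject_id = "S01") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!all(is.finite(data))) stop("epoch data must be finite")
  if (length(times) != dim(data)[3]) {
    stop("length(times) must equal the number of samples")
  }
  dt <- diff(times)
  if (any(dt <= 0) || any(abs(dt - 1 / srate) > 1e-9)) {
    stop("`times` must be strictly increasing with spacing 1/srate")
  }
  if (nrow(layout$channels) != dim(data)[2]) {
    stop("layout has ", nrow(layout$channels), " channels but data has ",
         dim(data)[2])
  }
  if (nrow(trials) != dim(data)[1]) {
    stop("trial table has ", nrow(trials), " rows but data has ",
         dim(data)[1], " trials")
  }
  structure(
    list(
      data = data, times = as.numeric(times), srate = srate,
      layout = layout, trials = tibble::as_tibble(trials),
      subject_id = subject_id
    ),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_epochs> subject ", x$subject_id, ": ", d[1], " trials x ", d[2],
      " channels x ", d[3], " samples @ ", x$srate, " Hz, t = [",
      round(x$times[1], 4), ", ", round(x$times[length(x$times)], 4),
      "] s\n", sep = "")
  invisible(x)
}

# Time axis implied by an epoch window and sampling rate: first sample at
# epoch_window[1], last sample <= epoch_window[2].
epoch_times <- function(epoch_window, srate) {
  n <- floor((epoch_window[2] - epoch_window[1]) * srate + 1e-9) + 1
  epoch_window[1] + (seq_len(n) - 1) / srate
}
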