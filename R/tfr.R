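#' Time-frequency configuration
#'
#' Settings for the sliding-window Hann time-frequency decomposition. The
#' window length adapts to frequency as `n_cycles / f` seconds (default
#' three cycles), trading frequency resolution for the temporal resolution
#' needed to separate pre- from post-stimulus power changes.
#'
#' @param freqs Frequency grid, Hz (default 2-30 Hz in 1 Hz steps).
#' @param n_cycles Cycles per window (window length `n_cycles / f`).
#' @param time_step Output time-grid step, s (grid is anchored at 0 so
#'   target onset is always a grid point).
#' @param taper Taper name; only `"hann"` is implemented.
#' @param tmin,tmax Optional limits (s) of the output time grid; `NULL`
#'   covers the whole epoch.
#' @return A list of class `tfr_config`.
#' @export
tfr_config <- function(freqs = 2:30, n_cycles = 3, time_step = 0.05,
                       taper = "hann", tmin = NULL, tmax = NULL) {
  stopifnot(all(freqs > 0), n_cycles >= 1, time_step > 0)
  taper <- match.arg(taper, "hann")
  structure(
    list(freqs = as.numeric(freqs), n_cycles = n_cycles,
         time_step = time_step, taper = taper, tmin = tmin, tmax = tmax),
    class = "tfr_config"
  )
}

#' Power map container
#'
#' Power indexed trials (or per-subject averages) x channels x frequencies
#' x timepoints. Timepoints whose analysis window overruns the epoch are
#' `NA` ("mark-undefined" edge policy); `NA`s propagate through baseline
#' normalization and band averaging so edge-contaminated estimates never
#' enter the statistics.
#'
#' @param values 4-D numeric array, trials x channels x freqs x times.
#' @param freqs,times Grid vectors matching dims 3 and 4.
#' @param channels Channel names matching dim 2.
#' @param units `"raw"` (non-negative) or `"relative"` (change from
#'   baseline, >= -1).
#' @param trials Optional trial tibble carried along for grouping.
#' @return An object of class `power_map`.
#' @export
power_map <- function(values, freqs, times, channels, units = "raw",
                      trials = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 4)
  stopifnot(dim(values)[2] == length(channels),
            dim(values)[3] == length(freqs),
            dim(values)[4] == length(times))
  if (units == "raw" && any(values < 0, na.rm = TRUE)) {
    stop("raw power must be non-negative")
  }
  if (units == "relative" && any(values < -1 - 1e-12, na.rm = TRUE)) {
    stop("relative power change must be >= -1")
  }
  structure(
    list(values = values, freqs = as.numeric(freqs),
         times = as.numeric(times), channels = channels, units = units,
         trials = trials),
    class = "power_map"
  )
}

#' @export
print.power_map <- function(x, ...) {
  d <- dim(x$values)
  cat("<power_map> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " freqs x ", d[4], " times (", x$units, "), ",
      sum(is.na(x$values[1, 1, , ])), " masked freq-time points\n", sep = "")
  invisible(x)
}

# odd window length in samples for frequency f
tfr_window_length <- function(f, n_cycles, srate) {
  2L * as.integer(round((n_cycles / f * srate - 1) / 2)) + 1L
}

#' Per-trial spectral power with adaptive Hann windows
#'
#' For each trial, channel, frequency `f` and output timepoint `t`, extracts
#' the segment of length `n_cycles / f` (rounded to an odd sample count,
#' centered on `t`), multiplies it by a Hann taper, and takes the squared
#' magnitude of the discrete Fourier projection onto frequency `f`. The
#' single-frequency projection is mathematically identical to the `f` bin
#' of a windowed Fourier transform but avoids computing unused bins. Power
#' is scaled by `(2 / sum(taper))^2` so a unit-amplitude sinusoid at `f`
#' yields power ~1 (any fixed scale cancels in baseline normalization).
#'
#' Timepoints whose window overruns the epoch are masked `NA`; a frequency
#' whose window exceeds the whole epoch is fully masked with a warning.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param cfg A [tfr_config()].
#' @return A `"raw"` [power_map()].
#' @examples
#' p <- sim_params(trials_per_condition = 3, n_channels = 16)
#' ep <- simulate_subject(generate_schedule(p, 1), build_layout(16), p, 2)
#' pw <- compute_power(ep, tfr_config(freqs = 8:12))
#' @export
compute_power <- function(epochs, cfg = tfr_config()) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(cfg, "tfr_config"))
  times <- epochs$times
  srate <- epochs$srate
  n_samp <- length(times)
  d <- dim(epochs$data)
  n_trials <- d[1]; n_ch <- d[2]

  step <- cfg$time_step
  lo <- max(times[1], cfg$tmin %||% times[1])
  hi <- min(times[n_samp], cfg$tmax %||% times[n_samp])
  t_out <- step * seq(ceiling(lo / step - 1e-9), floor(hi / step + 1e-9))
  n_t <- length(t_out)
  n_f <- length(cfg$freqs)

  # flatten to (trials*channels) x samples for BLAS-backed projections
  M <- matrix(epochs$data, nrow = n_trials * n_ch, ncol = n_samp)
  vals <- array(NA_real_, dim = c(n_trials, n_ch, n_f, n_t))

  longest_ok <- tfr_window_length(min(cfg$freqs), cfg$n_cycles, srate)
  if (longest_ok > n_samp) {
    warning("window (", cfg$n_cycles, " cycles) at ", min(cfg$freqs),
            " Hz exceeds the epoch; those frequencies are fully masked")
  }

  for (k in seq_len(n_f)) {
    f <- cfg$freqs[k]
    L <- tfr_window_length(f, cfg$n_cycles, srate)
    if (L > n_samp) next
    h <- (L - 1L) %/% 2L
    w <- hann_window(L)
    scale <- (2 / sum(w))^2
    ph <- 2 * pi * f * (seq_len(L) - 1) / srate
    kc <- w * cos(ph)
    ks <- w * sin(ph)
    centers <- as.integer(round((t_out - times[1]) * srate)) + 1L
    ok <- which(centers - h >= 1L & centers + h <= n_samp)
    if (length(ok) == 0) next
    # one banded sparse kernel per frequency: column j holds the windowed
    # cosine (first block) / sine (second block) for output timepoint j
    rows <- as.vector(outer(seq_len(L) - h - 1L, centers[ok], "+"))
    K <- Matrix::sparseMatrix(
      i = rep(rows, 2L),
      j = rep(seq_len(2L * length(ok)), each = L),
      x = c(rep(kc, length(ok)), rep(ks, length(ok))),
      dims = c(n_samp, 2L * length(ok))
    )
    proj <- as.matrix(M %*% K)
    nk <- length(ok)
    vals[, , k, ok] <- scale * (proj[, seq_len(nk)]^2 +
                                  proj[, nk + seq_len(nk)]^2)
  }

  power_map(vals, cfg$freqs, t_out, epochs$layout$channels$name,
            units = "raw", trials = epochs$trials)
}

hann_window <- function(L) {
  if (L == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / (L - 1)))
}

#' Relative-change baseline normalization
#'
#' Converts raw power to relative change from baseline:
#' `(power - baseline) / baseline`, where the baseline is the mean raw
#' power over the baseline timepoints and over all trials of the
#' normalization unit (per channel and frequency). Averaging over trials
#' before dividing follows the "average power at baseline" reading and
#' avoids instability from near-zero single-trial baselines.
#'
#' @param power A `"raw"` [power_map()].
#' @param baseline_window Two-element window (s), e.g. `c(-2.2, -1.8)` for
#'   the 400-ms precue alpha baseline or `c(-0.7, -0.3)` for the pretarget
#'   theta baseline.
#' @param groups Optional factor (length = trials) defining normalization
#'   units (e.g. subject x condition cells); `NULL` treats all trials as
#'   one unit.
#' @return A `"relative"` [power_map()].
#' @export
baseline_relative <- function(power, baseline_window, groups = NULL) {
  stopifnot(inherits(power, "power_map"))
  if (power$units != "raw") stop("power is already baseline-normalized")
  sel <- power$times >= baseline_window[1] - 1e-9 &
    power$times <= baseline_window[2] + 1e-9
  if (!any(sel)) stop("baseline window contains no timepoints")
  d <- dim(power$values)
  if (is.null(groups)) groups <- rep(1L, d[1])
  groups <- as.factor(groups)
  if (length(groups) != d[1]) stop("`groups` must have one entry per trial")

  vals <- power$values
  out <- vals
  for (g in levels(groups)) {
    tr <- which(groups == g)
    base_block <- vals[tr, , , sel, drop = FALSE]
    # mean over trials and baseline timepoints -> channels x freqs
    base <- apply(base_block, c(2, 3), mean)
    if (any(is.na(base))) {
      stop("baseline window overlaps masked (edge) timepoints")
    }
    if (any(base <= 0)) stop("zero baseline power")
    out[tr, , , ] <- sweep(vals[tr, , , , drop = FALSE], c(2, 3), base,
                           "/") - 1
  }
  power_map(out, power$freqs, power$times, power$channels,
            units = "relative", trials = power$trials)
}

#' Average power over a frequency band
#'
#' Unweighted mean over the grid frequencies inside the closed band (e.g.
#' alpha 8-12 Hz, theta 4-6 Hz). `NA` masks propagate: a timepoint is
#' masked in the band average if any contributing frequency is masked.
#'
#' @param power A [power_map()].
#' @param band Two-element frequency interval, Hz.
#' @return A [power_map()] with a single (band-center) frequency.
#' @export
band_average <- function(power, band) {
  stopifnot(inherits(power, "power_map"))
  sel <- power$freqs >= band[1] - 1e-9 & power$freqs <= band[2] + 1e-9
  if (!any(sel)) stop("band [", band[1], ", ", band[2],
                      "] contains no grid frequencies")
  d <- dim(power$values)
  sub <- power$values[, , sel, , drop = FALSE]
  nf <- sum(sel)
  flat <- aperm(sub, c(3, 1, 2, 4))
  dim(flat) <- c(nf, d[1] * d[2] * d[4])
  avg <- array(colMeans(flat), dim = c(d[1], d[2], 1L, d[4])) # NA if any freq masked
  power_map(avg, mean(power$freqs[sel]), power$times, power$channels,
            units = power$units, trials = power$trials)
}
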