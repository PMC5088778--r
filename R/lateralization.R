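#' Hemisphere flip-and-pool
#'
#' Re-expresses every trial in a common contralateral/ipsilateral frame:
#' trials with a left-sided target have their channel values exchanged
#' within each left-right mirror pair (midline channels unchanged), while
#' right-target trials pass through. In the pooled result the right
#' hemisphere carries activity ipsilateral to the target and the left
#' hemisphere carries contralateral activity.
#'
#' @param power A [power_map()] (any units).
#' @param target_side Character vector (length = trials) of `"left"` /
#'   `"right"`; defaults to `power$trials$target_side`.
#' @param layout The [build_layout()] the power map was computed on; every
#'   non-midline channel must belong to a mirror pair.
#' @return A [power_map()] of identical shape; the original side per trial
#'   is kept in `power$trials$target_side` (provenance).
#' @export
flip_pool <- function(power, target_side = NULL, layout) {
  stopifnot(inherits(power, "power_map"), inherits(layout, "eeg_layout"))
  target_side <- target_side %||% power$trials$target_side
  d <- dim(power$values)
  if (length(target_side) != d[1]) {
    stop("`target_side` must have one entry per trial")
  }
  if (!identical(layout$channels$name, power$channels)) {
    stop("layout channels do not match power map channels")
  }
  mi <- mirror_index(layout)
  if (any(is.na(mi))) stop("unpaired non-midline channel in layout")
  out <- power$values
  left <- which(target_side == "left")
  if (length(left)) out[left, , , ] <- power$values[left, mi, , , drop = FALSE]
  power_map(out, power$freqs, power$times, power$channels,
            units = power$units, trials = power$trials)
}

#' Average a power map over trial groups
#'
#' Collapses the trial dimension to one average per group (e.g. per
#' condition), yielding subject-level condition maps for the group
#' statistics.
#'
#' @param power A [power_map()].
#' @param groups Factor of length trials; `NULL` averages all trials.
#' @return A [power_map()] with one "trial" per group level (in level
#'   order); `trials` holds a tibble of group labels and trial counts.
#' @export
average_trials <- function(power, groups = NULL) {
  d <- dim(power$values)
  if (is.null(groups)) groups <- rep("all", d[1])
  groups <- as.factor(groups)
  lev <- levels(groups)
  out <- array(NA_real_, dim = c(length(lev), d[2], d[3], d[4]))
  for (i in seq_along(lev)) {
    tr <- which(groups == lev[i])
    block <- power$values[tr, , , , drop = FALSE]
    dim(block) <- c(length(tr), d[2] * d[3] * d[4])
    out[i, , , ] <- colMeans(block)
  }
  power_map(out, power$freqs, power$times, power$channels,
            units = power$units,
            trials = tibble::tibble(group = lev,
                                    n_trials = as.integer(table(groups)[lev])))
}

#' Alpha lateralization index
#'
#' Mean power ipsilateral minus mean power contralateral to the target over
#' a channel set and time window, computed on flip-and-pooled data (one
#' "trial" per subject). The channel set is usually the extent of a
#' significant cluster; left-hemisphere members are mapped to their
#' right-hemisphere mirrors so each selected pair contributes its ipsi
#' minus contra difference once. Midline channels are ignored (they carry
#' no lateralization).
#'
#' @param lat A flip-and-pooled, band-averaged [power_map()] whose trial
#'   dimension indexes subjects.
#' @param layout The matching [build_layout()].
#' @param channels Character vector of selected channel names.
#' @param window Two-element time window, s.
#' @return Tibble with `subject` (row index of `lat`) and `index`.
#' @export
lateralization_index <- function(lat, layout, channels, window) {
  stopifnot(inherits(lat, "power_map"))
  mi <- mirror_index(layout)
  names(mi) <- layout$channels$name
  hemi <- layout$channels$hemisphere
  names(hemi) <- layout$channels$name
  channels <- intersect(channels, layout$channels$name)
  reps <- unique(c(
    channels[hemi[channels] == "R"],
    layout$channels$name[mi[channels[hemi[channels] == "L"]]]
  ))
  tsel <- which(lat$times >= window[1] - 1e-9 & lat$times <= window[2] + 1e-9)
  if (length(reps) == 0 || length(tsel) == 0) {
    stop("empty channel/time selection for the lateralization index")
  }
  ipsi_i <- match(reps, lat$channels)
  contra_i <- mi[reps]
  n_subj <- dim(lat$values)[1]
  idx <- vapply(seq_len(n_subj), function(s) {
    mean(lat$values[s, ipsi_i, 1, tsel]) -
      mean(lat$values[s, contra_i, 1, tsel])
  }, numeric(1))
  tibble::tibble(subject = seq_len(n_subj), index = idx)
}

#' High-minus-low lateralization difference
#'
#' Per-subject difference between the lateralization index under
#' high-similarity and low-similarity distraction; more negative values
#' mean less lateralization when distraction is high.
#'
#' @param idx_high,idx_low Tibbles from [lateralization_index()] with
#'   matching subjects.
#' @return Tibble with `subject` and `difference`.
#' @export
lateralization_difference <- function(idx_high, idx_low) {
  if (!identical(idx_high$subject, idx_low$subject)) {
    stop("subject sets of the two indices do not match")
  }
  tibble::tibble(subject = idx_high$subject,
                 difference = idx_high$index - idx_low$index)
}

#' Spearman rank correlation with a reproducible outlier rule
#'
#' Rank correlation (average ranks for ties) with a p-value from the t
#' approximation, reported both with all points and after removing points
#' flagged by a deterministic outlier rule: under `"mad3"`, a point is an
#' outlier if its robust z score (distance from the median in units of the
#' scaled MAD) exceeds 3 on either axis. The rule replaces by-eye outlier
#' identification with an auditable criterion; both results are always
#' reported.
#'
#' @param x,y Numeric vectors (same length, n >= 5), e.g. per-subject
#'   distractor cost and lateralization difference.
#' @param outlier_policy `"mad3"` or `"none"`.
#' @return An object of class `lat_correlation`; see [tidy.lat_correlation()].
#' @export
spearman_corr <- function(x, y, outlier_policy = c("mad3", "none")) {
  outlier_policy <- match.arg(outlier_policy)
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("need at least 5 paired observations")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]

  outliers <- integer(0)
  if (outlier_policy == "mad3") {
    zx <- robust_z(x); zy <- robust_z(y)
    outliers <- which(zx > 3 | zy > 3)
  }

  full <- spearman_rho_p(x, y)
  trimmed <- if (length(outliers) > 0 && length(x) - length(outliers) >= 5) {
    spearman_rho_p(x[-outliers], y[-outliers])
  } else {
    full
  }
  structure(
    list(
      with_outliers = full,
      without_outliers = trimmed,
      outliers = outliers,
      n = length(x),
      policy = outlier_policy,
      data = tibble::tibble(x = x, y = y,
                            outlier = seq_along(x) %in% outliers)
    ),
    class = "lat_correlation"
  )
}

robust_z <- function(v) {
  m <- stats::median(v)
  s <- stats::mad(v) # 1.4826 * median absolute deviation
  if (s == 0) return(ifelse(v == m, 0, Inf))
  abs(v - m) / s
}

spearman_rho_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n,
                note = "undefined: zero variance in ranks"))
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n, note = NA_character_)
}

#' @export
print.lat_correlation <- function(x, ...) {
  w <- x$with_outliers; wo <- x$without_outliers
  cat("<lat_correlation> Spearman rank correlation (", x$policy,
      " outlier rule)\n", sep = "")
  cat(sprintf("  all points      (n=%d): rho = %.3f, p = %.4f\n",
              w$n, w$rho, w$p))
  cat(sprintf("  outliers removed (n=%d): rho = %.3f, p = %.4f  [%s]\n",
              wo$n, wo$rho, wo$p,
              if (length(x$outliers)) paste("removed", length(x$outliers))
              else "none flagged"))
  invisible(x)
}

#' Tidy a lateralization-behavior correlation
#'
#' @param x A `lat_correlation` object.
#' @param ... Unused.
#' @return Tibble with one row per analysis (`"with_outliers"`,
#'   `"without_outliers"`): `estimate` (rho), `p.value`, `n`, `n_outliers`.
#' @export
tidy.lat_correlation <- function(x, ...) {
  tibble::tibble(
    analysis = c("with_outliers", "without_outliers"),
    estimate = c(x$with_outliers$rho, x$without_outliers$rho),
    p.value = c(x$with_outliers$p, x$without_outliers$p),
    n = c(x$with_outliers$n, x$without_outliers$n),
    n_outliers = length(x$outliers)
  )
}

#' Distractor cost from uncued trials
#'
#' Per-subject mean reaction time on retained (correct, no eye movement)
#' uncued high-similarity trials minus retained uncued low-similarity
#' trials, in ms. Cued trials in the input are ignored.
#'
#' @param behavior Trial tibble with columns `subject`, `cue_presence`,
#'   `distractor`, `rt_ms`, `correct`, `eye_movement`.
#' @return Tibble with `subject` and `cost_ms`; subjects with an empty
#'   high- or low-similarity cell are dropped with a warning.
#' @export
distractor_cost <- function(behavior) {
  b <- pool_similarity(behavior)
  b <- dplyr::filter(b, .data$cue_presence == "uncued", .data$correct,
                     !.data$eye_movement)
  out <- b |>
    dplyr::group_by(.data$subject, .data$similarity) |>
    dplyr::summarise(rt = mean(.data$rt_ms), n = dplyr::n(),
                     .groups = "drop") |>
    tidyr::pivot_wider(id_cols = "subject", names_from = "similarity",
                       values_from = c("rt", "n"))
  if (!all(c("rt_high", "rt_low") %in% names(out))) {
    stop("no retained uncued trials in one similarity condition")
  }
  bad <- is.na(out$rt_high) | is.na(out$rt_low)
  if (any(bad)) {
    warning("dropping subject(s) with an empty cell: ",
            toString(out$subject[bad]))
    out <- out[!bad, ]
  }
  tibble::tibble(subject = out$subject, cost_ms = out$rt_high - out$rt_low)
}
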