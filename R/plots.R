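#' Plot a time-frequency power map
#'
#' Heatmap of trial-averaged power over time and frequency for one channel
#' (or the average of a channel group). Masked edge points are blank.
#'
#' @param object A [power_map()].
#' @param channels Channel name(s) to average; default all.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_map <- function(object, channels = NULL, ...) {
  ch_idx <- if (is.null(channels)) seq_along(object$channels) else
    match(channels, object$channels)
  if (any(is.na(ch_idx))) stop("unknown channel(s)")
  d <- dim(object$values)
  block <- object$values[, ch_idx, , , drop = FALSE]
  dim(block) <- c(d[1] * length(ch_idx), d[3] * d[4])
  avg <- matrix(colMeans(block), d[3], d[4])
  df <- tidyr::expand_grid(freq = object$freqs, time = object$times)
  df$power <- as.vector(avg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b",
      midpoint = if (object$units == "relative") 0 else NA,
      name = if (object$units == "relative") "rel. change" else "power"
    ) +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a cluster permutation test
#'
#' Channel-by-time heatmap of the observed paired t map with members of
#' significant clusters (Monte Carlo p below the test's alpha) marked.
#'
#' @param object A `cluster_test` from [permutation_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_test <- function(object, ...) {
  tm <- object$tmap
  chs <- object$channels %||% as.character(seq_len(nrow(tm)))
  tms <- object$times %||% seq_len(ncol(tm))
  df <- tidyr::expand_grid(channel = factor(chs, levels = chs),
                           time = tms)
  df$t <- as.vector(t(tm)) # channel varies slowest, matching expand_grid
  sig <- object$clusters[object$clusters$p_mc < object$alpha, ]
  marks <- if (nrow(sig)) {
    v <- unlist(sig$members)
    tibble::tibble(
      channel = factor(chs[(v - 1) %% nrow(tm) + 1], levels = chs),
      time = tms[(v - 1) %/% nrow(tm) + 1]
    )
  } else {
    NULL
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$channel,
                                        fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "t") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(marks)) {
    p <- p + ggplot2::geom_point(
      data = marks, ggplot2::aes(x = .data$time, y = .data$channel),
      inherit.aes = FALSE, size = 0.6, color = "black"
    )
  }
  p
}

#' Scatter plot of the brain-behavior correlation
#'
#' Distractor cost against the high-minus-low lateralization difference,
#' with MAD-flagged outliers highlighted.
#'
#' @param object A `lat_correlation` from [spearman_corr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lat_correlation <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               color = .data$outlier)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "black",
                                           `TRUE` = "#d01c8b"),
                                name = "outlier") +
    ggplot2::labs(
      x = "distractor cost (ms)",
      y = "lateralization difference (high - low)",
      subtitle = sprintf("Spearman rho = %.2f (without outliers %.2f)",
                         object$with_outliers$rho,
                         object$without_outliers$rho)
    ) +
    ggplot2::theme_minimal()
}

#' Sensor layout plot
#'
#' Scalp positions with the neighborhood graph; posterior and midfrontal
#' groups are colored.
#'
#' @param object An [build_layout()] layout.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_layout <- function(object, ...) {
  ch <- object$channels
  ed <- which(object$adjacency & upper.tri(object$adjacency),
              arr.ind = TRUE)
  seg <- tibble::tibble(
    x = ch$x[ed[, 1]], y = ch$y[ed[, 1]],
    xend = ch$x[ed[, 2]], yend = ch$y[ed[, 2]]
  )
  ch$group <- ifelse(ch$name %in% object$posterior, "posterior",
                     ifelse(ch$name %in% object$midfrontal, "midfrontal",
                            "other"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          color = "grey80") +
    ggplot2::geom_point(data = ch,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$group), size = 3) +
    ggplot2::geom_text(data = ch,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name),
                       vjust = -1, size = 2.8) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
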