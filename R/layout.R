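#' Sensor layout for a symmetric 10/20-style cap
#'
#' Builds a left/right symmetric EEG channel layout: sensor names, 2-D scalp
#' positions (unit head radius, nose up), the left-right mirror pairing used
#' by hemisphere flip-and-pool, and a planar-distance neighborhood graph used
#' by the spatio-temporal cluster test.
#'
#' Sensors are drawn from a 34-channel 10/20 master set in a fixed priority
#' order that guarantees the posterior (parieto-occipital) and midfrontal
#' groups exist at every supported size, so small layouts remain usable for
#' alpha-lateralization and midfrontal-theta analyses.
#'
#' @param n_channels Number of sensors (8 to 34). The default 32 is a
#'   symmetric subset of a 64-channel cap, kept small for tractable
#'   simulation.
#' @param neighbor_dist Planar distance within which two sensors count as
#'   neighbors. `NULL` (default) chooses the distance adaptively:
#'   `max(1.6 * median, 1.01 * max)` of the nearest-neighbor distances, which
#'   guarantees every sensor has at least one neighbor at any layout size.
#' @return An object of class `eeg_layout`: a list with
#'   \describe{
#'     \item{channels}{tibble with `name`, `x`, `y`, `hemisphere`
#'       (`"L"`, `"R"` or `"M"` for midline) and `mirror` (the name of the
#'       mirror-image sensor; midline sensors mirror to themselves).}
#'     \item{adjacency}{symmetric, irreflexive logical matrix of neighbors.}
#'     \item{posterior, midfrontal}{character vectors naming the default
#'       channel groups for alpha and theta analyses.}
#'     \item{neighbor_dist}{the distance actually used.}
#'   }
#' @examples
#' lay <- build_layout(16)
#' lay$channels
#' @export
build_layout <- function(n_channels = 32, neighbor_dist = NULL) {
  if (!is.numeric(n_channels) || length(n_channels) != 1 || n_channels < 8) {
    stop("`n_channels` must be a single number >= 8 (need posterior and midfrontal groups)")
  }
  n_channels <- as.integer(n_channels)
  master <- master_channel_table()
  units <- master_unit_order()

  picked <- character(0)
  for (u in units) {
    if (length(picked) + length(u) <= n_channels) picked <- c(picked, u)
    if (length(picked) == n_channels) break
  }
  if (length(picked) < n_channels) {
    stop("cannot build a symmetric layout with ", n_channels,
         " channels (maximum ", nrow(master), ")")
  }

  channels <- master[match(picked, master$name), , drop = FALSE]
  channels <- channels[order(match(channels$name, master$name)), ]
  rownames(channels) <- NULL
  channels <- tibble::as_tibble(channels)

  d <- as.matrix(stats::dist(cbind(channels$x, channels$y)))
  diag(d) <- Inf
  nnd <- apply(d, 1, min)
  if (is.null(neighbor_dist)) {
    neighbor_dist <- max(1.6 * stats::median(nnd), 1.01 * max(nnd))
  }
  adjacency <- d <= neighbor_dist
  diag(adjacency) <- FALSE
  dimnames(adjacency) <- list(channels$name, channels$name)
  if (any(rowSums(adjacency) == 0)) {
    stop("`neighbor_dist` = ", format(neighbor_dist),
         " leaves isolated sensors; increase it")
  }

  posterior <- intersect(
    c("P7", "P3", "Pz", "P4", "P8", "PO7", "PO3", "POz", "PO4", "PO8",
      "O1", "Oz", "O2"),
    channels$name
  )
  midfrontal <- intersect(c("Fz", "FCz", "FC1", "FC2", "Cz"), channels$name)

  structure(
    list(
      channels = channels,
      adjacency = adjacency,
      posterior = posterior,
      midfrontal = midfrontal,
      neighbor_dist = neighbor_dist
    ),
    class = "eeg_layout"
  )
}

#' @export
print.eeg_layout <- function(x, ...) {
  cat("<eeg_layout> ", nrow(x$channels), " channels (",
      sum(x$channels$hemisphere == "M"), " midline), ",
      "posterior group: ", length(x$posterior),
      ", midfrontal group: ", length(x$midfrontal), "\n", sep = "")
  cat("neighbor distance ", format(x$neighbor_dist, digits = 3),
      "; mean degree ", format(mean(rowSums(x$adjacency)), digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Mirror permutation of a layout
#'
#' Integer permutation `p` such that channel `i`'s mirror-image sensor is
#' channel `p[i]`; midline sensors map to themselves. Applying it twice is
#' the identity.
#'
#' @param layout An `eeg_layout`.
#' @return Integer vector of length `n_channels`.
#' @export
mirror_index <- function(layout) {
  stopifnot(inherits(layout, "eeg_layout"))
  match(layout$channels$mirror, layout$channels$name)
}

# 34-channel master table: approximate 2-D projections of the extended 10/20
# positions, unit head radius, nose along +y.
master_channel_table <- function() {
  pair <- function(l, r, x, y) {
    data.frame(
      name = c(l, r), x = c(-x, x), y = c(y, y),
      hemisphere = c("L", "R"), mirror = c(r, l),
      stringsAsFactors = FALSE
    )
  }
  mid <- function(nm, y) {
    data.frame(name = nm, x = 0, y = y, hemisphere = "M", mirror = nm,
               stringsAsFactors = FALSE)
  }
  rbind(
    pair("Fp1", "Fp2", 0.31, 0.95),
    pair("F7", "F8", 0.81, 0.59),
    pair("F3", "F4", 0.40, 0.57),
    mid("Fz", 0.55),
    pair("FC5", "FC6", 0.63, 0.30),
    pair("FC1", "FC2", 0.22, 0.33),
    mid("FCz", 0.35),
    pair("T7", "T8", 1.00, 0.00),
    pair("C3", "C4", 0.50, 0.00),
    mid("Cz", 0.00),
    pair("CP5", "CP6", 0.63, -0.30),
    pair("CP1", "CP2", 0.22, -0.33),
    pair("P7", "P8", 0.81, -0.59),
    pair("P3", "P4", 0.40, -0.57),
    mid("Pz", -0.55),
    pair("PO7", "PO8", 0.55, -0.82),
    pair("PO3", "PO4", 0.29, -0.79),
    mid("POz", -0.75),
    pair("O1", "O2", 0.31, -0.95),
    mid("Oz", -0.95)
  )
}

# Priority units (pairs add 2 sensors, midline sensors add 1). Posterior and
# midfrontal sensors come first so every size >= 8 contains both groups.
master_unit_order <- function() {
  list(
    c("O1", "O2"), "Oz", c("PO7", "PO8"), "Fz", "FCz",
    c("P3", "P4"), c("P7", "P8"), "Pz", c("C3", "C4"), "Cz",
    c("CP1", "CP2"), c("F3", "F4"), c("FC1", "FC2"),
    c("CP5", "CP6"), c("FC5", "FC6"), c("T7", "T8"), c("F7", "F8"),
    "POz", c("PO3", "PO4"), c("Fp1", "Fp2")
  )
}
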