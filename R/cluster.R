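#' Paired t-statistic map
#'
#' Pointwise dependent-samples t statistic over subjects: for each
#' channel-time point, the one-sample t of `a - b`. Points with zero
#' variance across subjects get `t = 0` when the mean difference is zero
#' and signed infinity otherwise (such points count as supra-threshold with
#' their sign in cluster formation). Points that are `NA` for any subject
#' (masked edges) are `NA`.
#'
#' @param a,b Numeric arrays, subjects x channels x timepoints, same
#'   subjects in the same order.
#' @return Channels x timepoints matrix of t values.
#' @export
paired_tmap <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)), length(dim(a)) == 3)
  n <- dim(a)[1]
  if (n < 2) stop("need at least 2 subjects")
  d <- a - b
  dim(d) <- c(n, prod(dim(a)[2:3]))
  tvec <- tstat_from_diffs(colSums(d), colSums(d^2), n)
  matrix(tvec, dim(a)[2], dim(a)[3])
}

# t from per-point sum and sum of squares of the n differences
tstat_from_diffs <- function(s, ss, n) {
  m <- s / n
  v <- pmax((ss - n * m^2) / (n - 1), 0)
  t <- ifelse(v > 0, m / sqrt(v / n),
              ifelse(m == 0, 0, sign(m) * Inf))
  t[!is.finite(s)] <- NA_real_
  t
}

# Edge list of the channel x time product graph: (c,t)~(c,t+/-1) and
# (c,t)~(c',t) for spatial neighbors c~c'. Vertices numbered channel-major:
# v = (t-1)*n_ch + c. Returns a 2 x E integer matrix.
product_graph_edges <- function(adjacency, n_time) {
  n_ch <- nrow(adjacency)
  nb <- which(adjacency & upper.tri(adjacency), arr.ind = TRUE)
  t_off <- rep((seq_len(n_time) - 1L) * n_ch, each = nrow(nb))
  sp1 <- rep(nb[, 1], n_time) + t_off
  sp2 <- rep(nb[, 2], n_time) + t_off
  if (n_time > 1) {
    ch <- seq_len(n_ch)
    tm1 <- rep((seq_len(n_time - 1L) - 1L) * n_ch, each = n_ch) + ch
    tm2 <- tm1 + n_ch
  } else {
    tm1 <- integer(0); tm2 <- integer(0)
  }
  rbind(c(sp1, tm1), c(sp2, tm2))
}

# Connected same-sign supra-threshold components of a t vector on the
# product graph. Returns integer component labels (0 = sub-threshold).
label_components <- function(tvec, threshold, edges) {
  supra <- !is.na(tvec) & abs(tvec) > threshold
  verts <- which(supra)
  nv <- length(verts)
  labels <- integer(length(tvec))
  if (nv == 0) return(labels)
  pos <- tvec > 0
  keep <- supra[edges[1, ]] & supra[edges[2, ]] &
    (pos[edges[1, ]] == pos[edges[2, ]])
  id <- integer(length(tvec))
  id[verts] <- seq_len(nv)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (any(keep)) {
    e1 <- id[edges[1, keep]]
    e2 <- id[edges[2, keep]]
    for (k in seq_along(e1)) {
      r1 <- find(e1[k]); r2 <- find(e2[k])
      if (r1 != r2) parent[r2] <- r1
    }
  }
  roots <- vapply(seq_len(nv), find, integer(1))
  labels[verts] <- match(roots, unique(roots))
  labels
}

# Maximum absolute cluster mass of a t vector (0 when nothing is supra).
max_cluster_mass <- function(tvec, threshold, edges) {
  labels <- label_components(tvec, threshold, edges)
  on_v <- labels > 0
  if (!any(on_v)) return(0)
  masses <- rowsum(tvec[on_v], labels[on_v])
  max(abs(masses))
}

#' Form supra-threshold clusters
#'
#' Groups same-signed channel-time points with `|t|` above the
#' cluster-forming threshold into connected clusters. Two points are
#' connected when they share a channel and are adjacent in time, or share
#' a timepoint and are spatial neighbors. Each cluster's mass is the sum
#' of its member t values.
#'
#' @param tmap Channels x timepoints t matrix (e.g. from [paired_tmap()]).
#' @param threshold_t Positive cluster-forming threshold on `|t|`.
#' @param graph Channel adjacency: a logical matrix or an [build_layout()]
#'   object.
#' @return Tibble with one row per cluster: `cluster`, `sign`, `mass`,
#'   `n_points`, `channels` (list of channel indices), `time_idx` (list of
#'   time indices), plus a `members` list-column of vertex indices into
#'   `tmap`. Empty tibble when nothing exceeds the threshold.
#' @export
form_clusters <- function(tmap, threshold_t, graph) {
  stopifnot(threshold_t > 0)
  adjacency <- if (inherits(graph, "eeg_layout")) graph$adjacency else graph
  stopifnot(is.matrix(adjacency), nrow(adjacency) == nrow(tmap))
  edges <- product_graph_edges(adjacency, ncol(tmap))
  tvec <- as.vector(tmap)
  labels <- label_components(tvec, threshold_t, edges)
  cluster_table(tvec, labels, nrow(tmap))
}

cluster_table <- function(tvec, labels, n_ch) {
  ids <- setdiff(unique(labels), 0L)
  if (length(ids) == 0) {
    return(tibble::tibble(
      cluster = integer(0), sign = integer(0), mass = numeric(0),
      n_points = integer(0), channels = list(), time_idx = list(),
      members = list()
    ))
  }
  rows <- lapply(ids, function(i) {
    v <- which(labels == i)
    mass <- sum(tvec[v])
    ch <- sort(unique((v - 1L) %% n_ch + 1L))
    ti <- sort(unique((v - 1L) %/% n_ch + 1L))
    tibble::tibble(
      sign = as.integer(sign(mass)), mass = mass, n_points = length(v),
      channels = list(ch), time_idx = list(ti), members = list(v)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-abs(out$mass)), ]
  out$cluster <- seq_len(nrow(out))
  out[, c("cluster", "sign", "mass", "n_points", "channels", "time_idx",
          "members")]
}

#' Spatio-temporal cluster-based permutation test
#'
#' Nonparametric paired test across channels and timepoints. Observed
#' clusters are formed from the dependent-samples t map at the
#' cluster-forming threshold (default: two-sided pointwise p < 0.05, i.e.
#' `qt(0.975, n - 1)`). The null distribution of the maximum absolute
#' cluster mass is built by randomly flipping the sign of each subject's
#' condition difference -- algebraically identical to swapping that
#' subject's condition labels -- and recomputing the t map and its largest
#' cluster mass. Each observed cluster gets the Monte Carlo p-value
#' `(# null maxima >= |mass| + 1) / (n_perm + 1)`; taking the maximum over
#' both signs makes the test two-tailed. When `2^n <= n_perm` all sign
#' assignments are enumerated instead (exact test, seed-independent).
#'
#' @param a,b Subjects x channels x timepoints arrays (paired).
#' @param graph Channel adjacency matrix or [build_layout()].
#' @param n_perm Number of random permutations (default 1000; fewer than
#'   100 draws a warning).
#' @param alpha Significance level used when summarizing (`glance`) and
#'   reporting significant clusters.
#' @param seed Optional integer seed for the random permutations.
#' @param threshold_t Cluster-forming threshold; default `qt(0.975, n-1)`.
#' @param channels,times Optional labels for reporting.
#' @param exhaustive `NULL` (default) switches to exhaustive enumeration
#'   automatically when `2^n <= n_perm`; `FALSE` forces Monte Carlo
#'   sampling (validation use), `TRUE` forces enumeration.
#' @return An object of class `cluster_test`: the cluster tibble (with
#'   `p_mc`), the observed `tmap`, the permutation `null_max` distribution,
#'   `n_perm`, `threshold`, and an `exhaustive` flag.
#' @export
permutation_test <- function(a, b, graph, n_perm = 1000, alpha = 0.05,
                             seed = NULL, threshold_t = NULL,
                             channels = NULL, times = NULL,
                             exhaustive = NULL) {
  stopifnot(identical(dim(a), dim(b)), length(dim(a)) == 3)
  n <- dim(a)[1]
  if (n < 2) stop("need at least 2 subjects")
  if (n_perm < 100) warning("fewer than 100 permutations; p-values are coarse")
  adjacency <- if (inherits(graph, "eeg_layout")) graph$adjacency else graph
  n_ch <- dim(a)[2]; n_time <- dim(a)[3]
  stopifnot(nrow(adjacency) == n_ch)
  threshold_t <- threshold_t %||% stats::qt(0.975, df = n - 1)

  d <- a - b
  dim(d) <- c(n, n_ch * n_time)
  valid <- colSums(is.na(d)) == 0
  d[, !valid] <- 0 # excluded below via NA reinsertion
  ss <- colSums(d^2)

  edges <- product_graph_edges(adjacency, n_time)
  tvec_obs <- tstat_from_diffs(colSums(d), ss, n)
  tvec_obs[!valid] <- NA_real_
  labels <- label_components(tvec_obs, threshold_t, edges)
  clusters <- cluster_table(tvec_obs, labels, n_ch)

  exhaustive <- exhaustive %||% (2^n <= n_perm)
  signs <- if (exhaustive) {
    as.matrix(do.call(expand.grid, rep(list(c(-1, 1)), n)))
  } else {
    with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                           n_perm, n))
  }
  n_used <- nrow(signs)

  null_max <- numeric(n_used)
  for (p in seq_len(n_used)) {
    s <- colSums(signs[p, ] * d)
    tv <- tstat_from_diffs(s, ss, n)
    tv[!valid] <- NA_real_
    null_max[p] <- max_cluster_mass(tv, threshold_t, edges)
  }

  if (nrow(clusters) > 0) {
    clusters$p_mc <- vapply(clusters$mass, function(m) {
      if (exhaustive) {
        mean(null_max >= abs(m) - 1e-12)
      } else {
        (sum(null_max >= abs(m) - 1e-12) + 1) / (n_used + 1)
      }
    }, numeric(1))
  } else {
    clusters$p_mc <- numeric(0)
  }

  structure(
    list(
      clusters = clusters,
      tmap = matrix(tvec_obs, n_ch, n_time,
                    dimnames = list(channels, times)),
      null_max = null_max,
      n_perm = n_used,
      threshold = threshold_t,
      alpha = alpha,
      exhaustive = exhaustive,
      channels = channels,
      times = times
    ),
    class = "cluster_test"
  )
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("<cluster_test> ", nrow(x$clusters), " cluster(s), threshold |t| > ",
      format(x$threshold, digits = 4), ", ",
      if (x$exhaustive) "exhaustive " else "", x$n_perm,
      " permutations\n", sep = "")
  if (nrow(x$clusters)) {
    print(tidy(x), n = 5)
  }
  invisible(x)
}

#' Tidy a cluster permutation test
#'
#' @param x A `cluster_test` object.
#' @param ... Unused.
#' @return Tibble with one row per cluster: `cluster`, `sign`, `mass`
#'   (summed t), `n_points`, `p.value`, and -- when time labels were
#'   supplied -- `time_start` / `time_end` of the cluster extent.
#' @export
tidy.cluster_test <- function(x, ...) {
  cl <- x$clusters
  out <- tibble::tibble(
    cluster = cl$cluster, sign = cl$sign, mass = cl$mass,
    n_points = cl$n_points, p.value = cl$p_mc
  )
  if (!is.null(x$times) && nrow(cl)) {
    out$time_start <- vapply(cl$time_idx, function(i) x$times[min(i)],
                             numeric(1))
    out$time_end <- vapply(cl$time_idx, function(i) x$times[max(i)],
                           numeric(1))
  }
  out
}

#' @rdname tidy.cluster_test
#' @return `glance()`: one-row tibble with `n_clusters`,
#'   `n_significant` (at `alpha`), `min_p`, `n_perm`, `threshold`,
#'   `exhaustive`.
#' @export
glance.cluster_test <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$p_mc < x$alpha),
    min_p = if (nrow(x$clusters)) min(x$clusters$p_mc) else NA_real_,
    n_perm = x$n_perm,
    threshold = x$threshold,
    exhaustive = x$exhaustive
  )
}
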