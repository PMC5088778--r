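# Independent oracles used to validate the analysis implementations.
# These deliberately use different algorithms/code paths than the package.

# Windowed single-frequency power by direct summation: Hann-tapered DFT
# coefficient at frequency f, squared, with the package's normalization.
oracle_tfr_power <- function(x, srate, f, t_center, times, n_cycles = 3) {
  L <- 2L * as.integer(round((n_cycles / f * srate - 1) / 2)) + 1L
  ci <- which.min(abs(times - t_center))
  h <- (L - 1L) %/% 2L
  if (ci - h < 1 || ci + h > length(x)) return(NA_real_)
  seg <- x[(ci - h):(ci + h)]
  n <- seq_len(L) - 1
  w <- if (L == 1) 1 else 0.5 * (1 - cos(2 * pi * n / (L - 1)))
  coef <- sum(seg * w * exp(-2i * pi * f * n / srate))
  (2 / sum(w))^2 * Mod(coef)^2
}

# Flood-fill (BFS) cluster partition over the explicit channel-time product
# graph; returns an integer label matrix (0 = below threshold).
oracle_flood_fill <- function(tmap, threshold, adjacency) {
  n_ch <- nrow(tmap); n_t <- ncol(tmap)
  supra <- !is.na(tmap) & abs(tmap) > threshold
  labels <- matrix(0L, n_ch, n_t)
  cur <- 0L
  for (c0 in seq_len(n_ch)) {
    for (t0 in seq_len(n_t)) {
      if (!supra[c0, t0] || labels[c0, t0] > 0L) next
      cur <- cur + 1L
      queue <- list(c(c0, t0))
      labels[c0, t0] <- cur
      s0 <- tmap[c0, t0] > 0
      while (length(queue) > 0) {
        v <- queue[[1]]; queue <- queue[-1]
        cc <- v[1]; tt <- v[2]
        cand <- list()
        if (tt > 1) cand <- c(cand, list(c(cc, tt - 1)))
        if (tt < n_t) cand <- c(cand, list(c(cc, tt + 1)))
        for (nb in which(adjacency[cc, ])) cand <- c(cand, list(c(nb, tt)))
        for (u in cand) {
          if (supra[u[1], u[2]] && labels[u[1], u[2]] == 0L &&
              (tmap[u[1], u[2]] > 0) == s0) {
            labels[u[1], u[2]] <- cur
            queue <- c(queue, list(u))
          }
        }
      }
    }
  }
  labels
}

# Canonical multiset of (mass, size) pairs for comparing partitions.
cluster_signature <- function(tvec, labels) {
  on_v <- labels > 0
  if (!any(on_v)) return(character(0))
  masses <- rowsum(tvec[on_v], labels[on_v])
  sizes <- table(labels[on_v])
  sort(paste(round(masses[order(as.integer(rownames(masses)))], 8),
             as.integer(sizes[order(as.integer(names(sizes)))])))
}

# Full within-subject ANOVA via base aov() error strata.
oracle_rm_anova_aov <- function(df) {
  df$A <- factor(df$A); df$B <- factor(df$B); df$subject <- factor(df$subject)
  fit <- summary(aov(y ~ A * B + Error(subject / (A * B)), data = df))
  get_f <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  c(A = get_f("Error: subject:A", "A"),
    B = get_f("Error: subject:B", "B"),
    AB = get_f("Error: subject:A:B", "A:B"))
}

# Spearman rho by the explicit sum-of-squared-rank-differences formula
# (valid without ties).
oracle_spearman_d2 <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# A small random adjacency that is symmetric, irreflexive and connected
# enough for cluster tests.
random_adjacency <- function(n_ch, p = 0.3) {
  a <- matrix(FALSE, n_ch, n_ch)
  for (i in seq_len(n_ch - 1)) a[i, i + 1] <- a[i + 1, i] <- TRUE # chain
  extra <- matrix(runif(n_ch^2) < p, n_ch, n_ch)
  extra[lower.tri(extra, diag = TRUE)] <- FALSE
  a <- a | extra | t(extra)
  diag(a) <- FALSE
  a
}

# Tiny default simulation parameters for fast structural tests.
tiny_params <- function(...) {
  sim_params(n_subjects = 3, trials_per_condition = 6, n_channels = 16, ...)
}
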