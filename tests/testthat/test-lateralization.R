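toy_power <- function(vals, lay, sides, times = c(0, 0.05, 0.1)) {
  # vals: trials x channels matrix replicated over times
  arr <- array(rep(vals, length(times)),
               c(nrow(vals), ncol(vals), 1, length(times)))
  power_map(arr, 10, times, lay$channels$name, units = "relative",
            trials = tibble::tibble(target_side = sides))
}

test_that("flip-and-pool swaps mirror pairs for left targets only", {
  lay <- build_layout(8)
  o1 <- match("O1", lay$channels$name); o2 <- match("O2", lay$channels$name)
  vals <- matrix(0, 2, 8)
  vals[, o1] <- 2; vals[, o2] <- 1
  pm <- toy_power(vals, lay, c("right", "left"))
  fp <- flip_pool(pm, layout = lay)
  # right-target trial untouched
  expect_equal(fp$values[1, , 1, 1], pm$values[1, , 1, 1])
  # left-target trial: O1 and O2 exchanged
  expect_equal(fp$values[2, o1, 1, 1], 1)
  expect_equal(fp$values[2, o2, 1, 1], 2)
  # involution: flipping twice restores the original
  fp2 <- flip_pool(fp, layout = lay)
  expect_equal(fp2$values[2, , 1, 1], pm$values[2, , 1, 1])
  # midline unchanged
  oz <- match("Oz", lay$channels$name)
  expect_equal(fp$values[, oz, 1, 1], pm$values[, oz, 1, 1])
})

test_that("flip-pool preserves the per-pair multiset of values", {
  lay <- build_layout(16)
  mi <- mirror_index(lay)
  set.seed(5)
  vals <- matrix(runif(6 * 16, -0.5, 1.5), 6, 16)
  sides <- sample(c("left", "right"), 6, replace = TRUE)
  fp <- flip_pool(toy_power(vals, lay, sides), layout = lay)
  for (tr in 1:6) {
    for (c1 in which(lay$channels$hemisphere == "L")) {
      pair_before <- sort(c(vals[tr, c1], vals[tr, mi[c1]]))
      pair_after <- sort(c(fp$values[tr, c1, 1, 1],
                           fp$values[tr, mi[c1], 1, 1]))
      expect_equal(pair_after, pair_before)
    }
  }
})

test_that("lateralization index is ipsi minus contra over the selection", {
  lay <- build_layout(16)
  hemi <- lay$channels$hemisphere
  vals <- matrix(0, 1, 16)
  fp <- toy_power(vals, lay, "right")
  # symmetric data -> 0
  idx0 <- lateralization_index(fp, lay, lay$posterior, c(0, 0.1))
  expect_equal(idx0$index, 0)
  # ipsi (right) uniformly +0.2, contra (left) -0.1 -> 0.3
  vals[1, hemi == "R"] <- 0.2
  vals[1, hemi == "L"] <- -0.1
  idx <- lateralization_index(toy_power(vals, lay, "right"), lay,
                              lay$posterior, c(0, 0.1))
  expect_equal(idx$index, 0.3)
  # antisymmetric under swapping the hemispheres
  mi <- mirror_index(lay)
  idx_sw <- lateralization_index(toy_power(vals[, mi, drop = FALSE], lay,
                                           "right"),
                                 lay, lay$posterior, c(0, 0.1))
  expect_equal(idx_sw$index, -idx$index)
  # left-hemisphere selections map to their mirrors (same result)
  left_sel <- lay$posterior[hemi[match(lay$posterior,
                                       lay$channels$name)] == "L"]
  idx_left <- lateralization_index(toy_power(vals, lay, "right"), lay,
                                   left_sel, c(0, 0.1))
  right_sel <- lay$channels$name[mi[match(left_sel, lay$channels$name)]]
  idx_right <- lateralization_index(toy_power(vals, lay, "right"), lay,
                                    right_sel, c(0, 0.1))
  expect_equal(idx_left$index, idx_right$index)
  expect_error(lateralization_index(fp, lay, "Oz", c(0, 0.1)), "empty")
})

test_that("lateralization difference is elementwise high minus low", {
  h <- tibble::tibble(subject = 1:3, index = c(0.1, 0.2, 0.0))
  l <- tibble::tibble(subject = 1:3, index = c(0.4, 0.2, -0.1))
  d <- lateralization_difference(h, l)
  expect_equal(d$difference, c(-0.3, 0, 0.1))
  expect_error(lateralization_difference(h, l[c(2, 1, 3), ]), "match")
})

test_that("zero-asymmetry cohorts have indices centered on zero", {
  p <- sim_params(n_subjects = 4, trials_per_condition = 6, n_channels = 8,
                  alpha_asymmetry = 0, theta_amp = 0, coupling_alpha = 0)
  lay <- build_layout(8)
  means <- numeric(10)
  for (k in 1:10) {
    plan <- cohort_plan(p, seed = 400 + k)
    idx <- numeric(nrow(plan))
    for (i in seq_len(nrow(plan))) {
      sub <- simulate_cohort_subject(p, lay, plan[i, ])
      ep <- sub$epochs
      pw <- compute_power(ep, tfr_config(freqs = 10, tmin = -2.2, tmax = 1))
      rel <- baseline_relative(pw, c(-2.2, -1.8))
      fp <- flip_pool(rel, layout = lay)
      avg <- average_trials(fp)
      idx[i] <- lateralization_index(avg, lay, lay$posterior,
                                     c(0.3, 0.9))$index
    }
    means[k] <- mean(idx)
  }
  tt <- t.test(means)
  expect_gt(tt$p.value, 0.01) # centered on zero across cohorts
})

test_that("spearman_corr matches closed forms and flags MAD outliers", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- x^2
  expect_equal(spearman_corr(x, y)$with_outliers$rho, 1)
  expect_equal(spearman_corr(x, rev(y))$with_outliers$rho, -1)

  set.seed(77)
  x8 <- rnorm(8); y8 <- rnorm(8)
  sc <- spearman_corr(x8, y8, outlier_policy = "none")
  expect_equal(sc$with_outliers$rho, oracle_spearman_d2(x8, y8),
               tolerance = 1e-12)
  ref <- suppressWarnings(cor.test(x8, y8, method = "spearman"))
  expect_equal(sc$with_outliers$rho, unname(ref$estimate), tolerance = 1e-12)

  # an extreme point is flagged and removed in the trimmed analysis
  x_out <- c(rnorm(9), 100)
  y_out <- c(rnorm(9), -100)
  sc2 <- spearman_corr(x_out, y_out)
  expect_identical(sc2$outliers, 10L)
  expect_identical(sc2$without_outliers$n, 9L)
  expect_error(spearman_corr(1:4, 1:4), "at least 5")
  # zero variance in ranks is reported as undefined
  und <- spearman_corr(rep(1, 6), rnorm(6))
  expect_true(is.na(und$with_outliers$rho))
})
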