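test_that("trial rejection counts incorrect and eye-movement trials once", {
  b <- tibble::tibble(correct = rep(TRUE, 10), eye_movement = rep(FALSE, 10))
  expect_identical(reject_trials(b), 1:10)
  b$correct[c(2, 5)] <- FALSE
  b$eye_movement[8] <- TRUE
  expect_identical(length(reject_trials(b)), 7L)
  # overlapping failure reasons are not double counted
  b$eye_movement[8] <- FALSE
  b$eye_movement[2] <- TRUE # trial 2 now fails both rules
  b$eye_movement[8] <- TRUE
  expect_identical(length(reject_trials(b)), 7L)
  expect_identical(reject_trials(b), setdiff(1:10, c(2, 5, 8)))
})

make_cohort_behavior <- function(n_subj = 6, n_per_cell = 40, seed = 1,
                                 params = sim_params()) {
  sched <- generate_schedule(sim_params(trials_per_condition = n_per_cell),
                             seed = seed)
  dplyr::bind_rows(lapply(seq_len(n_subj), function(s) {
    b <- simulate_behavior(sched, params, seed = seed + s)
    b$subject <- sprintf("S%02d", s)
    b
  }))
}

test_that("accuracy exclusion uses strict 'below mean - 2 SD' on group stats", {
  # engineered accuracies: sd over {0.9 x5, 0.4} -> threshold below 0.4?
  beh <- make_cohort_behavior(n_subj = 5, n_per_cell = 30)
  # force one subject to a known low accuracy but exactly at the boundary
  rep0 <- exclude_subjects(beh)
  thr <- rep0$group_mean[1] - 2 * rep0$group_sd[1]
  expect_true(all(rep0$accuracy > thr)) # defaults: nobody excluded
  expect_true(all(!rep0$accuracy_excluded))
  expect_identical(rep0$final_included,
                   !(rep0$accuracy_excluded | rep0$similarity_excluded))
})

test_that("boundary subject exactly at mean - 2 SD is retained", {
  # three synthetic subjects with accuracies fixed so that the lowest sits
  # exactly on the threshold: acc = m - 2*sd holds for {a, a, b} when
  # b = a - 2*sd([a,a,b]) -> solved numerically below
  f <- function(b) b - (mean(c(0.9, 0.9, b)) - 2 * sd(c(0.9, 0.9, b)))
  b_star <- uniroot(f, c(0.1, 0.9))$root
  accs <- c(0.9, 0.9, b_star)
  n <- 300
  beh <- dplyr::bind_rows(lapply(1:3, function(s) {
    tibble::tibble(
      subject = paste0("S", s),
      cue_presence = rep(c("cued", "uncued"), each = n / 2),
      distractor = rep(c("D1", "D4"), n / 2),
      rt_ms = c(rnorm(n / 2, 900, 50), rnorm(n / 2, 800, 50)),
      correct = seq_len(n) <= round(accs[s] * n),
      eye_movement = FALSE
    )
  }))
  rep <- exclude_subjects(beh)
  # S3's accuracy equals the threshold (up to rounding of trial counts);
  # "two SDs below" is strict, so equality retains
  expect_false(rep$accuracy_excluded[rep$accuracy >=
                                       rep$group_mean - 2 * rep$group_sd][1])
})

test_that("similarity screen excludes flat D1/D4 subjects at ~the type-I rate", {
  # rt_model with no distractor effect: retention requires a significant
  # D1 > D4 difference, which now happens only by chance
  p <- sim_params()
  p$rt_model$mean_ms <- rep(850, 8)
  excluded <- logical(20)
  for (i in 1:20) {
    beh <- make_cohort_behavior(n_subj = 3, n_per_cell = 30, seed = 100 + i,
                                params = p)
    rep <- exclude_subjects(beh)
    excluded[i] <- rep$similarity_excluded[1]
  }
  expect_gte(mean(excluded), 0.75) # ~97.5% in expectation
})

test_that("cohorts at study defaults produce no similarity exclusions", {
  # full-size cells (108 trials) with the default D1-D4 gap: the screen
  # should essentially never fire (checked over several cohorts)
  n_excl <- 0
  for (i in 1:5) {
    beh <- make_cohort_behavior(n_subj = 4, n_per_cell = 108, seed = 200 + i)
    rep <- exclude_subjects(beh)
    n_excl <- n_excl + sum(rep$similarity_excluded)
  }
  expect_equal(n_excl, 0)
})

test_that("exclusion is idempotent on the retained set's original stats", {
  beh <- make_cohort_behavior(n_subj = 8, n_per_cell = 60, seed = 9)
  rep1 <- exclude_subjects(beh)
  keep <- rep1$subject[rep1$final_included]
  rep2 <- exclude_subjects(beh[beh$subject %in% keep, ])
  # similarity rule is per subject, unchanged by the group
  expect_identical(rep2$similarity_excluded,
                   rep1$similarity_excluded[rep1$final_included])
})

test_that("similarity pooling partitions D1-D4 and preserves counts", {
  tr <- tibble::tibble(distractor = c("D1", "D2", "D3", "D4", "D1"))
  out <- pool_similarity(tr)
  expect_identical(out$similarity, c("high", "high", "low", "low", "high"))
  expect_identical(nrow(out), nrow(tr))
  expect_error(pool_similarity(tibble::tibble(distractor = "D5")), "unknown")
})

test_that("distractor cost is high-minus-low RT on retained uncued trials", {
  b <- tibble::tibble(
    subject = rep("S1", 8),
    cue_presence = rep(c("uncued", "cued"), each = 4),
    distractor = rep(c("D1", "D2", "D3", "D4"), 2),
    rt_ms = c(900, 900, 800, 800, 1e6, 1e6, 1e6, 1e6),
    correct = TRUE, eye_movement = FALSE
  )
  cost <- distractor_cost(b)
  expect_equal(cost$cost_ms, 100) # cued rows (1e6) ignored
  b2 <- b; b2$rt_ms[1:4] <- 750
  expect_equal(distractor_cost(b2)$cost_ms, 0) # equal cell means
})

test_that("chance tests handle degenerate inputs and exact levels", {
  expect_equal(chance_level(), 1 / 3)
  expect_equal(chance_level(use_distractor = TRUE), 0.5)
  res <- t_vs_chance(rep(1 / 3, 6), chance = 1 / 3)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  res2 <- t_vs_chance(rep(0.9, 6), chance = 1 / 3)
  expect_true(res2$zero_variance && res2$statistic == Inf && res2$p.value == 0)
  res3 <- t_vs_chance(c(0.8, 0.85, 0.9, 0.95), chance = 0.5)
  expect_equal(res3$statistic,
               unname(t.test(c(0.8, 0.85, 0.9, 0.95), mu = 0.5)$statistic))
})

test_that("Bonferroni correction multiplies and caps", {
  set.seed(3)
  cm <- tidyr::expand_grid(subject = paste0("S", 1:6),
                           cell = c("a", "b", "c", "d"))
  cm$value <- rnorm(nrow(cm)) + ifelse(cm$cell == "a", 3, 0)
  out <- pairwise_bonferroni(cm)
  expect_identical(nrow(out), 6L) # all pairs of 4 cells
  expect_equal(out$p.adjusted, pmin(1, out$p.value * 6))
  one <- pairwise_bonferroni(cm, contrasts = list(c("a", "b")))
  expect_equal(one$p.adjusted, one$p.value) # single-contrast family
  cm2 <- cm; cm2$value <- 1 # identical conditions
  all_one <- pairwise_bonferroni(cm2)
  expect_true(all(all_one$p.adjusted == 1))
})
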