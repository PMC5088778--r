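test_that("paired t map matches the hand formula and its symmetries", {
  a <- array(0, c(4, 1, 1)); b <- array(0, c(4, 1, 1))
  a[, 1, 1] <- c(1.0, 2.0, 0.5, 1.5)
  b[, 1, 1] <- c(0.2, 1.1, 0.4, 0.9)
  tm <- paired_tmap(a, b)
  d <- a[, 1, 1] - b[, 1, 1]
  expect_equal(tm[1, 1], mean(d) / (sd(d) / 2), tolerance = 1e-12)
  expect_equal(tm[1, 1], 3.3717, tolerance = 1e-4) # frozen hand value
  # a = b -> all zeros; swapping negates
  expect_true(all(paired_tmap(a, a) == 0))
  expect_equal(paired_tmap(b, a), -tm)
  # zero variance with nonzero mean -> signed infinity
  a2 <- a; a2[, 1, 1] <- b[, 1, 1] + 1
  expect_identical(paired_tmap(a2, b)[1, 1], Inf)
})

test_that("clusters follow spatial-temporal connectivity", {
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- TRUE # chain A-B-C
  tm <- matrix(0, 3, 1)
  expect_identical(nrow(form_clusters(tm, 2, adj)), 0L)
  tm[, 1] <- c(3, 3, 3)
  cl <- form_clusters(tm, 2, adj)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_points, 3L)
  expect_equal(cl$mass, 9)
  # opposite signs never join even when adjacent
  tm[, 1] <- c(3, -3, 3)
  cl2 <- form_clusters(tm, 2, adj)
  expect_identical(nrow(cl2), 3L)
  # temporal adjacency joins across timepoints on the same channel
  tm2 <- matrix(0, 3, 3)
  tm2[1, ] <- 3
  cl3 <- form_clusters(tm2, 2, adj)
  expect_identical(nrow(cl3), 1L)
  expect_identical(cl3$n_points, 3L)
})

test_that("cluster partition matches a flood-fill oracle on 1000 instances", {
  set.seed(31)
  for (i in 1:1000) {
    n_ch <- 5; n_t <- 10
    adj <- random_adjacency(n_ch)
    tm <- matrix(rnorm(n_ch * n_t, sd = 2), n_ch, n_t)
    thr <- runif(1, 1, 3)
    cl <- form_clusters(tm, thr, adj)
    labels <- oracle_flood_fill(tm, thr, adj)
    # same clusters as multisets of (mass, size)
    got <- sort(paste(round(cl$mass, 8), cl$n_points))
    want <- cluster_signature(as.vector(tm), as.vector(labels))
    expect_identical(got, want)
  }
})

test_that("Monte Carlo p is close to the exhaustive p on the same data", {
  set.seed(55)
  n <- 12
  adj <- random_adjacency(6)
  a <- array(rnorm(n * 6 * 8), c(n, 6, 8))
  b <- array(rnorm(n * 6 * 8), c(n, 6, 8))
  a[, 2:3, 3:5] <- a[, 2:3, 3:5] + 1.1 # moderate effect -> mid-range p
  exact <- permutation_test(a, b, adj, n_perm = 4096, exhaustive = TRUE)
  mc <- permutation_test(a, b, adj, n_perm = 2000, seed = 8,
                         exhaustive = FALSE)
  expect_true(mc$exhaustive == FALSE && exact$exhaustive == TRUE)
  expect_identical(exact$n_perm, 4096L)
  p_ex <- exact$clusters$p_mc[1]
  p_mc <- mc$clusters$p_mc[1]
  expect_lt(abs(p_ex - p_mc), 0.02)
  # exhaustive mode ignores the seed entirely
  exact2 <- permutation_test(a, b, adj, n_perm = 4096, seed = 999,
                             exhaustive = TRUE)
  expect_identical(exact$clusters, exact2$clusters)
})

test_that("a saturating injected effect reaches the smallest possible p", {
  set.seed(66)
  n <- 16 # 2^16 >> 300 permutations -> Monte Carlo branch
  adj <- random_adjacency(8)
  a <- array(rnorm(n * 8 * 6), c(n, 8, 6))
  b <- array(rnorm(n * 8 * 6), c(n, 8, 6))
  a[, 1:4, ] <- a[, 1:4, ] + 10 # 10 SD block
  res <- permutation_test(a, b, adj, n_perm = 300, seed = 4)
  top <- res$clusters[1, ]
  expect_equal(top$p_mc, 1 / 301)
  expect_true(all(1:4 %in% top$channels[[1]]))
})

test_that("results are deterministic under a fixed seed", {
  set.seed(9)
  a <- array(rnorm(8 * 5 * 6), c(8, 5, 6))
  b <- array(rnorm(8 * 5 * 6), c(8, 5, 6))
  adj <- random_adjacency(5)
  r1 <- permutation_test(a, b, adj, n_perm = 300, seed = 21)
  r2 <- permutation_test(a, b, adj, n_perm = 300, seed = 21)
  expect_identical(r1$null_max, r2$null_max)
  expect_identical(tidy(r1), tidy(r2))
})

test_that("the test is invariant to channel relabeling", {
  set.seed(12)
  n_ch <- 6
  a <- array(rnorm(7 * n_ch * 9), c(7, n_ch, 9))
  b <- array(rnorm(7 * n_ch * 9), c(7, n_ch, 9))
  a[, 1:2, 4:6] <- a[, 1:2, 4:6] + 2
  adj <- random_adjacency(n_ch)
  perm <- sample(n_ch)
  r1 <- permutation_test(a, b, adj, n_perm = 500, seed = 3)
  r2 <- permutation_test(a[, perm, , drop = FALSE],
                         b[, perm, , drop = FALSE],
                         adj[perm, perm], n_perm = 500, seed = 3)
  expect_equal(sort(r1$clusters$mass), sort(r2$clusters$mass))
  expect_equal(sort(r1$clusters$p_mc), sort(r2$clusters$p_mc))
})

test_that("masked (NA) points never enter clusters", {
  set.seed(44)
  a <- array(rnorm(6 * 4 * 5), c(6, 4, 5))
  b <- array(rnorm(6 * 4 * 5), c(6, 4, 5))
  a[, 1, ] <- a[, 1, ] + 10
  a[1, 1, 3] <- NA
  res <- permutation_test(a, b, random_adjacency(4), n_perm = 200, seed = 2)
  expect_true(is.na(res$tmap[1, 3]))
  members <- unlist(res$clusters$members)
  expect_false(((3 - 1) * 4 + 1) %in% members) # vertex (ch 1, t 3)
})

test_that("degenerate inputs raise the documented conditions", {
  a <- array(rnorm(10), c(1, 2, 5))
  expect_error(permutation_test(a, a, random_adjacency(2)), "2 subjects")
  a2 <- array(rnorm(3 * 2 * 5), c(3, 2, 5))
  expect_warning(permutation_test(a2, a2 * 0.9, random_adjacency(2),
                                  n_perm = 50), "100 permutations")
  expect_error(form_clusters(matrix(0, 2, 2), -1, random_adjacency(2)))
})
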