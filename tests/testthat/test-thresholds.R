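test_that("the pair set enumerates unordered pairs with canonical storage", {
  set.seed(1)
  m <- matrix(rpois(100, 5) + 1, 10)
  g <- runif(10, 0, 6)
  pairs <- build_pair_set(bray_curtis(m), g)
  expect_identical(nrow(pairs), 45L)
  expect_true(all(pairs$g_lo <= pairs$g_hi))
  expect_error(build_pair_set(bray_curtis(m), g[-1]), "length")
})

test_that("duplicated samples appear as zero-dissimilarity pairs", {
  m <- rbind(c(3, 1, 2), c(3, 1, 2), c(9, 0, 1))
  pairs <- build_pair_set(bray_curtis(m), c(1, 2, 3))
  expect_equal(min(pairs$d), 0)
})

test_that("a degenerate single-valued gradient is rejected at fitting", {
  set.seed(2)
  m <- matrix(rpois(120, 5) + 1, 12)
  pairs <- build_pair_set(bray_curtis(m), rep(2, 12))
  expect_true(all(pairs$g_lo == pairs$g_hi))
  pairs <- pairs[rep(1:nrow(pairs), 2), ]  # >= 50 pairs
  expect_error(fit_surface(pairs, seed = 1), "single-valued")
})

test_that("the surface recovers a linear dissimilarity law", {
  set.seed(3)
  n <- 200
  g <- runif(n, 0, 6)
  dm <- abs(outer(g, g, "-")) / diff(range(g))
  pairs <- build_pair_set(as.dist(dm), g)
  sm <- fit_surface(pairs, seed = 7)
  expect_gte(sm$r_squared, 0.9)
  expect_true(sm$baseline >= 0 && sm$baseline <= 1)
})

test_that("a constant response yields the zero r-squared contract", {
  set.seed(4)
  g <- runif(60, 0, 5)
  dm <- matrix(0.42, 60, 60); diag(dm) <- 0
  pairs <- build_pair_set(as.dist(dm), g)
  sm <- fit_surface(pairs, seed = 1)
  expect_equal(sm$r_squared, 0)
  th <- detect_thresholds(sm, grid = seq(0.2, 4.8, by = 0.2))
  expect_length(th$thresholds, 0)
})

test_that("surface predictions ignore the storage order of a pair", {
  set.seed(5)
  sim <- simulate_step_community(n_sites = 60, seed = 5)
  pairs <- build_pair_set(bray_curtis(sim$counts), sim$gradient)
  sm <- fit_surface(pairs, n_trees = 150, seed = 2)
  a <- predict_surface(sm, c(1.2, 4.1), c(4.8, 0.3))
  b <- predict_surface(sm, c(4.8, 0.3), c(1.2, 4.1))
  expect_equal(a, b)
})

test_that("a planted step change is localized within one grid step", {
  sim <- simulate_step_community(n_sites = 100, change_point = 3, seed = 11)
  pairs <- build_pair_set(bray_curtis(sim$counts), sim$gradient)
  sm <- fit_surface(pairs, n_trees = 300, seed = 3)
  th <- detect_thresholds(sm, grid = seq(0, 6, by = 0.2))
  expect_gte(length(th$thresholds), 1)
  expect_lte(min(abs(th$thresholds - 3)), 0.2)
})

test_that("oversized bands are rejected", {
  set.seed(6)
  sim <- simulate_step_community(n_sites = 60, seed = 6)
  pairs <- build_pair_set(bray_curtis(sim$counts), sim$gradient)
  sm <- fit_surface(pairs, n_trees = 100, seed = 1)
  expect_error(detect_thresholds(sm, grid = seq(0, 6, 0.5), band = 3.5),
               "band")
})
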