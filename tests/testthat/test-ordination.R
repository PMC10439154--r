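test_that("bray-curtis matches its closed forms", {
  m <- rbind(a = c(1, 1), b = c(1, 0), c = c(1, 1))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], 1 / 3)
  disj <- rbind(x = c(2, 0), y = c(0, 3))
  expect_equal(as.numeric(bray_curtis(disj)), 1)
})

test_that("bray-curtis is symmetric, bounded, and zero on the diagonal", {
  set.seed(5)
  for (rep in 1:3) {
    m <- matrix(rpois(48, 4) + (rep == 1), 8)
    m[rowSums(m) == 0, 1] <- 1
    d <- as.matrix(bray_curtis(m))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("an all-zero row is rejected with the sample named", {
  m <- rbind(ok = c(1, 2), empty = c(0, 0))
  expect_error(bray_curtis(m), "empty")
})

test_that("orthogonal predictors pass the VIF filter untouched", {
  env <- data.frame(a = rep(c(1, -1), 8), b = rep(c(1, 1, -1, -1), 4))
  expect_setequal(vif_filter(env, threshold = 5), c("a", "b"))
})

test_that("a duplicated variable loses exactly one copy", {
  set.seed(6)
  env <- data.frame(x = rnorm(20), z = rnorm(20))
  env$x_copy <- env$x
  kept <- suppressWarnings(vif_filter(env, threshold = 5))
  expect_identical(sum(c("x", "x_copy") %in% kept), 1L)
  expect_true("z" %in% kept)
})

test_that("dbRDA on euclidean distances equals classical RDA by direct eigendecomposition", {
  set.seed(42)
  Y <- matrix(runif(40), 10, 4)
  env <- data.frame(a = rnorm(10), b = rnorm(10))
  res <- dbrda_fit(dist(Y), env, n_perm = 99, seed = 1)
  # oracle: project centred responses on the predictors and eigendecompose
  Yc <- scale(Y, scale = FALSE)
  X <- scale(as.matrix(env), scale = FALSE)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  oracle <- eigen(crossprod(H %*% Yc), symmetric = TRUE)$values
  oracle <- oracle[oracle > 1e-10]
  expect_equal(unname(res$eig_constrained), oracle, tolerance = 1e-8)
})

test_that("an env column equal to the first PCoA axis is fully constrained on that axis", {
  set.seed(9)
  Y <- matrix(runif(36), 9, 4)
  d <- dist(Y)
  pc1 <- cmdscale(d, k = 1)[, 1]
  res <- dbrda_fit(d, data.frame(pc1 = pc1), n_perm = 99, seed = 1)
  # the single constrained axis carries exactly the first PCoA eigenvalue
  pcoa_eig <- suppressWarnings(cmdscale(d, k = 8, eig = TRUE))$eig
  expect_equal(unname(res$eig_constrained[1]), pcoa_eig[1], tolerance = 1e-6)
})

test_that("rank-deficient environments are rejected", {
  set.seed(2)
  Y <- matrix(runif(40), 10, 4)
  env <- data.frame(a = rnorm(10))
  env$b <- 2 * env$a
  expect_error(dbrda_fit(dist(Y), env, n_perm = 99, seed = 1),
               "rank deficient")
})

test_that("the constrained proportion is invariant to sample relabeling", {
  set.seed(11)
  Y <- matrix(rpois(60, 6) + 1, 12, 5)
  env <- data.frame(a = rnorm(12), b = rnorm(12))
  d <- bray_curtis(Y)
  r1 <- dbrda_fit(d, env, n_perm = 99, seed = 1)
  p <- sample(12)
  r2 <- dbrda_fit(as.dist(as.matrix(d)[p, p]), env[p, , drop = FALSE],
                  n_perm = 99, seed = 1)
  expect_equal(r1$proportion_constrained, r2$proportion_constrained,
               tolerance = 1e-10)
})

test_that("forward selection finds a planted driver before permuted decoys", {
  set.seed(31)
  n <- 40
  g <- seq(0, 1, length.out = n)
  # community composition drifts smoothly with g
  Y <- sapply(1:12, function(j) 50 * exp(-((g - (j - 1) / 11) / 0.25)^2))
  Y <- Y + matrix(rpois(n * 12, 2), n)
  env <- data.frame(driver = g)
  for (k in 1:5) env[[paste0("decoy", k)]] <- sample(g)
  fs <- forward_select(bray_curtis(Y), env, alpha = 0.05, n_perm = 199, seed = 5)
  expect_gte(nrow(fs), 1)
  expect_identical(fs$variable[1], "driver")
})

test_that("pure-noise environments mostly select nothing at alpha 0.05", {
  # per-variable false-positive rate ~alpha; with three candidates roughly
  # 14% of repeats admit something, so assert the rate, not a single draw
  set.seed(17)
  empty <- 0
  for (r in 1:10) {
    Y <- matrix(rpois(200, 5) + 1, 20, 10)
    env <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))
    fs <- forward_select(bray_curtis(Y), env, alpha = 0.05, n_perm = 99,
                         seed = r)
    empty <- empty + (nrow(fs) == 0)
  }
  expect_gte(empty, 7)
})

test_that("alpha of one admits every variable in decreasing gain order", {
  set.seed(23)
  Y <- matrix(rpois(80, 5) + 1, 10, 8)
  env <- data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  fs <- forward_select(bray_curtis(Y), env, alpha = 1, n_perm = 99, seed = 2)
  expect_setequal(fs$variable, c("a", "b", "c"))
})

test_that("too few permutations are rejected", {
  expect_error(forward_select(dist(matrix(runif(20), 5)),
                              data.frame(a = rnorm(5)), n_perm = 10, seed = 1),
               "19")
})
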