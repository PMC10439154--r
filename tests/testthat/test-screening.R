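test_that("the prefilter clamps oversized mtry and excludes constant ASVs", {
  set.seed(1)
  ds <- midi_dataset(seed = 31)
  sp <- split_pieces(ds)
  hmat <- sp$hmat
  hmat <- cbind(hmat, flat = rep(0.01, nrow(hmat)))
  expect_warning(
    pf <- rf_prefilter(hmat, sp$meta$chl_a_mg_L, seed = 2),
    "clamped")
  expect_false("flat" %in% pf$candidates)
  expect_lte(pf$hyperparams$mtry, ncol(hmat))
})

test_that("planted indicators enter the candidate list with top importance", {
  ds <- midi_dataset(seed = 33, n_groups = 2, true_lag = c(1, 2))
  sp <- split_pieces(ds)
  pf <- suppressWarnings(rf_prefilter(sp$hmat, sp$meta$chl_a_mg_L, seed = 3))
  ind <- c("ASV_ind1_a", "ASV_ind1_b", "ASV_ind2_a", "ASV_ind2_b")
  expect_true(all(ind %in% pf$candidates))
  expect_lte(max(match(ind, pf$candidates)), 10)
})

test_that("the prefilter refuses tiny sample sizes", {
  m <- matrix(runif(30), 10, 3)
  expect_error(rf_prefilter(m, rnorm(10), seed = 1), "20 samples")
})

test_that("grid-search ties resolve to the smallest lag then window", {
  # a constant candidate column gives identical metrics everywhere
  ds <- tiny_dataset(seed = 41)
  sp <- split_pieces(ds)
  series <- sp$hmat
  series[, "ASV_noise_001"] <- 0.05
  g <- grid_search_asv("ASV_noise_001", sp$design, series,
                       sp$meta$status_class, "classification",
                       train_idx = sp$train, test_idx = sp$test, seed = 1)
  expect_identical(g$spec$l, 0L)
  expect_identical(g$spec$w, 1L)
})

test_that("the grid search recovers a planted lag on clean data", {
  ds <- midi_dataset(seed = 45, n_stations = 60, true_lag = 2)
  sp <- split_pieces(ds)
  g <- grid_search_asv("ASV_ind1_a", sp$design, sp$hmat,
                       sp$meta$status_class, "classification",
                       train_idx = sp$train, test_idx = sp$test, seed = 4)
  expect_identical(g$spec$l, 2L)
})

test_that("a constant training response is rejected for regression", {
  ds <- tiny_dataset(seed = 47)
  sp <- split_pieces(ds)
  y <- rep(1.5, nrow(sp$meta))
  expect_error(
    grid_search_asv("ASV_noise_002", sp$design, sp$hmat, y, "regression",
                    train_idx = sp$train, test_idx = sp$test, seed = 1),
    "constant")
})

test_that("greedy screening accepts exactly the complementary indicators at zero noise", {
  # demonstrative frozen seeds; the property holds for most seeds and the
  # acceptance suite measures the rate on a full ensemble
  for (s in c(3, 5)) {
    ds <- simulate_dataset(seed = 100 + s)
    m <- greedy_screen(c("ASV_ind1_a", "ASV_ind2_a"), ds, seed = s)
    expect_equal(m$metric, 1)
    expect_setequal(vapply(m$accepted, `[[`, character(1), "asv_id"),
                    c("ASV_ind1_a", "ASV_ind2_a"))
  }
})

test_that("the held-out metric is non-decreasing along the inclusion order", {
  ds <- simulate_dataset(seed = 103)
  m <- greedy_screen(c("ASV_noise_004", "ASV_ind1_a", "ASV_noise_009",
                       "ASV_ind2_a"), ds, seed = 3)
  expect_true(all(diff(c(m$base_metric, m$trajectory)) > 0))
})

test_that("an all-noise candidate list accepts little and never reaches the ceiling", {
  ds <- simulate_dataset(seed = 104)
  m <- greedy_screen(paste0("ASV_noise_", sprintf("%03d", 1:5)), ds, seed = 2)
  expect_lt(m$metric, 1)
})

test_that("a class missing from the training split is a clear error", {
  ds <- tiny_dataset(seed = 51)
  # force the rarer class entirely into the downstream test segment
  ord <- order_by_flow(ds$metadata)
  n <- length(ord)
  cls <- rep("class1", n)
  cls[ord[seq(floor(0.85 * n) + 1, n)]] <- "class2"
  ds$metadata$status_class <- factor(cls, ordered = TRUE)
  expect_error(greedy_screen("ASV_noise_001", ds, seed = 1),
               "absent from the training split")
})

test_that("ensembles are reproducible from the master seed", {
  ds <- tiny_dataset(seed = 55)
  cands <- c("ASV_ind1_a", "ASV_noise_001", "ASV_noise_002")
  cfg <- screening_config(max_candidates = 3)
  e1 <- ensemble_screen(ds, n_runs = 3, config = cfg, seed = 9, candidates = cands)
  e2 <- ensemble_screen(ds, n_runs = 3, config = cfg, seed = 9, candidates = cands)
  expect_identical(e1$run_seeds, e2$run_seeds)
  expect_identical(lapply(e1$models, `[[`, "accepted"),
                   lapply(e2$models, `[[`, "accepted"))
  expect_identical(vapply(e1$models, `[[`, numeric(1), "metric"),
                   vapply(e2$models, `[[`, numeric(1), "metric"))
  expect_error(ensemble_screen(ds, n_runs = 2, seed = 1, candidates = character(0)),
               "empty candidate")
})

test_that("three-class responses are handled natively", {
  ds <- simulate_dataset(
    design = river_design(n_stations = 40),
    signal = planted_signal(n_groups = 2, clones_per_group = 1,
                            true_lag = c(1, 2),
                            response_cutpoints = c(0.5, 1.5)),
    n_noise_taxa = 20, library_size = 20000, seed = 61)
  expect_identical(nlevels(ds$metadata$status_class), 3L)
  m <- greedy_screen(c("ASV_ind1_a", "ASV_ind2_a"), ds, seed = 1)
  expect_gte(m$metric, 0.5)
})
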