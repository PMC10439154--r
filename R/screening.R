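#' Screening configuration
#'
#' Collects the tunable knobs of the spatio-temporal screening chain: the
#' (window, lag) grid searched per ASV, the ordered split fraction, the
#' strict-improvement tolerance of the greedy step, the number of top
#' prefilter candidates each run screens, and the boosted-model
#' hyperparameter space sampled by the ensemble.
#'
#' @param w_grid Integer windows searched (>= 1).
#' @param l_grid Integer lags searched (>= 0).
#' @param split Training fraction of the ordered split (the split occurs
#'   after the first `split` share of observations, upstream first).
#' @param tol Strict-improvement tolerance for accepting an ASV.
#' @param max_candidates Number of top prefilter candidates screened per run.
#' @param hyperparams Default boosting hyperparameters used when the
#'   ensemble does not sample them.
#' @param space Hyperparameter space for [ensemble_screen()]: ranges for
#'   `nrounds`, `max_depth` (uniform integers), `eta` (log-uniform),
#'   `subsample` (uniform).
#' @return List of class `screening_config`.
#' @export
screening_config <- function(w_grid = 1:5, l_grid = 0:5, split = 0.85,
                             tol = 1e-9, max_candidates = 16,
                             hyperparams = list(nrounds = 100L, max_depth = 3L,
                                                eta = 0.1, subsample = 0.9),
                             space = list(nrounds = c(30L, 90L),
                                          max_depth = c(2L, 5L),
                                          eta = c(0.05, 0.3),
                                          subsample = c(0.6, 1))) {
  stopifnot(all(w_grid >= 1), all(l_grid >= 0), split > 0, split < 1)
  structure(list(w_grid = as.integer(sort(w_grid)),
                 l_grid = as.integer(sort(l_grid)),
                 split = split, tol = tol,
                 max_candidates = as.integer(max_candidates),
                 hyperparams = hyperparams, space = space),
            class = "screening_config")
}

sample_hyperparams <- function(space) {
  ru <- function(r) stats::runif(1, r[1], r[2])
  list(
    nrounds = sample(seq(space$nrounds[1], space$nrounds[2]), 1),
    max_depth = sample(seq(space$max_depth[1], space$max_depth[2]), 1),
    eta = exp(ru(log(space$eta))),
    subsample = ru(space$subsample)
  )
}

# Fit a boosted model on the ordered split and return the held-out metric
# (accuracy for classification, R^2 for regression).
fit_eval_xgb <- function(X, y, task, hp, train_idx, test_idx, seed = 1) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (task == "classification") {
    lev <- levels(y)
    lab <- as.integer(y) - 1L
    if (length(unique(lab[train_idx])) < length(lev)) {
      stop("a status class is absent from the training split; ",
           "use a different split or dataset")
    }
    params <- list(max_depth = hp$max_depth, eta = hp$eta,
                   subsample = hp$subsample, nthread = 1,
                   seed = as.integer(seed))
    if (length(lev) == 2) {
      params$objective <- "binary:logistic"
    } else {
      params$objective <- "multi:softmax"
      params$num_class <- length(lev)
    }
    dtrain <- xgboost::xgb.DMatrix(X[train_idx, , drop = FALSE],
                                   label = lab[train_idx])
    booster <- xgboost::xgb.train(params = params, data = dtrain,
                                  nrounds = hp$nrounds, verbose = 0)
    pred <- stats::predict(booster, X[test_idx, , drop = FALSE])
    if (length(lev) == 2) pred <- as.integer(pred > 0.5)
    mean(pred == lab[test_idx])
  } else {
    yt <- as.numeric(y)
    if (stats::var(yt[train_idx]) == 0) {
      stop("response is constant on the training split")
    }
    params <- list(objective = "reg:squarederror", max_depth = hp$max_depth,
                   eta = hp$eta, subsample = hp$subsample, nthread = 1,
                   seed = as.integer(seed))
    dtrain <- xgboost::xgb.DMatrix(X[train_idx, , drop = FALSE],
                                   label = yt[train_idx])
    booster <- xgboost::xgb.train(params = params, data = dtrain,
                                  nrounds = hp$nrounds, verbose = 0)
    pred <- stats::predict(booster, X[test_idx, , drop = FALSE])
    ss_tot <- sum((yt[test_idx] - mean(yt[test_idx]))^2)
    if (ss_tot == 0) 0 else 1 - sum((yt[test_idx] - pred)^2) / ss_tot
  }
}

#' Random-forest prefilter of candidate ASVs
#'
#' Stage 1 tunes (mtry, ntree) by grid search of a supervised random forest
#' predicting chlorophyll *a* from the Hellinger-transformed ASV table on a
#' seeded 0.8/0.2 random split, taking the combination with the lowest test
#' mean squared error. Stage 2 refits the forest with the chosen
#' hyperparameters on all samples and computes permutation importance
#' (%IncMSE); candidate ASVs are those with %IncMSE strictly above 0, in
#' decreasing order. Sparse trigger taxa are invisible to a
#' real-versus-permuted synthetic-class forest, so the supervised
#' permutation importance — the measure %IncMSE natively belongs to — is
#' used for the ranking.
#'
#' @param matrix Hellinger-transformed samples x ASVs matrix (>= 20 samples).
#' @param chl Per-sample chlorophyll *a* values.
#' @param mtry_grid,ntree_grid Hyperparameter grids; `mtry` values larger
#'   than the number of ASVs are clamped with a warning.
#' @param split Training fraction of the stage-1 split.
#' @param seed Integer seed.
#' @return List with `hyperparams` (chosen mtry/ntree), `grid` (the stage-1
#'   search results), `importance` (per-ASV), and `candidates` (ordered ids).
#' @export
rf_prefilter <- function(matrix, chl, mtry_grid = c(400L, 1600L),
                         ntree_grid = c(30L, 100L), split = 0.8, seed = 1) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 20) stop("need at least 20 samples")
  stopifnot(length(chl) == nrow(matrix))
  p <- ncol(matrix)
  if (any(mtry_grid > p)) {
    warning("mtry values larger than the number of ASVs (", p, ") were clamped")
    mtry_grid <- pmin(mtry_grid, p)
  }
  mtry_grid <- sort(unique(as.integer(mtry_grid)))
  ntree_grid <- sort(unique(as.integer(ntree_grid)))
  set.seed(as.integer(seed))
  n <- nrow(matrix)
  train <- sort(sample.int(n, floor(split * n)))
  test <- setdiff(seq_len(n), train)
  grid <- expand.grid(mtry = mtry_grid, ntree = ntree_grid)
  grid$mse <- vapply(seq_len(nrow(grid)), function(i) {
    rf <- randomForest::randomForest(x = matrix[train, , drop = FALSE],
                                     y = chl[train], mtry = grid$mtry[i],
                                     ntree = grid$ntree[i])
    mean((stats::predict(rf, matrix[test, , drop = FALSE]) - chl[test])^2)
  }, numeric(1))
  best <- grid[which.min(grid$mse), ]
  # stage 2: permutation importance (%IncMSE) at the tuned hyperparameters
  rf2 <- randomForest::randomForest(x = matrix, y = chl, mtry = best$mtry,
                                    ntree = best$ntree, importance = TRUE)
  imp <- randomForest::importance(rf2, type = 1)[, 1]
  cand <- names(sort(imp[imp > 0], decreasing = TRUE))
  list(hyperparams = list(mtry = best$mtry, ntree = best$ntree),
       grid = grid, importance = imp, candidates = cand)
}

#' Grid search of (window, lag) for one candidate ASV
#'
#' Evaluates a boosted model on the current design matrix plus the candidate
#' ASV's engineered column for every (w, l) combination, on the ordered
#' train/test split, and returns the combination maximizing the held-out
#' metric. The grid is scanned lag-ascending then window-ascending with a
#' strict-improvement rule, so ties resolve to the smaller lag, then the
#' smaller window. Scanning stops early if a combination reaches perfect
#' classification accuracy (no later combination can strictly beat it).
#'
#' @param asv_id Candidate ASV.
#' @param design Current design matrix (from [base_design()] /
#'   [lagged_design_matrix()]).
#' @param series Samples x taxa matrix aligned with `design`.
#' @param response Response vector (factor for classification).
#' @param task "classification" or "regression".
#' @param w_grid,l_grid Search grids.
#' @param hyperparams Boosting hyperparameters.
#' @param train_idx,test_idx Ordered split indices.
#' @param seed Integer seed passed to the booster.
#' @return List with `spec` (asv_id, w, l), `metric`, and `grid` (all
#'   evaluated combinations).
#' @export
grid_search_asv <- function(asv_id, design, series, response, task,
                            w_grid = 1:5, l_grid = 0:5,
                            hyperparams = list(nrounds = 100L, max_depth = 3L,
                                               eta = 0.1, subsample = 0.9),
                            train_idx, test_idx, seed = 1) {
  if (!length(w_grid) || !length(l_grid)) stop("w_grid and l_grid must be nonempty")
  tr <- attr(design, "transect")
  if (is.null(tr)) stop("design must come from base_design() / lagged_design_matrix()")
  if (!asv_id %in% colnames(series)) stop("unknown ASV: ", asv_id)
  Xbase <- as.matrix(design)
  storage.mode(Xbase) <- "double"
  idx_by_tr <- split(seq_len(nrow(design)), tr)
  x <- series[, asv_id]
  best <- list(spec = NULL, metric = -Inf)
  ws <- integer(0); ls <- integer(0); ms <- numeric(0)
  for (l in sort(l_grid)) {
    for (w in sort(w_grid)) {
      col <- numeric(length(x))
      for (idx in idx_by_tr) {
        if (l >= length(idx)) stop("lag ", l, " is not smaller than a transect length")
        col[idx] <- lag_window_series(x[idx], w = w, l = l)
      }
      X <- cbind(Xbase, candidate = col)
      metric <- fit_eval_xgb(X, response, task, hyperparams,
                             train_idx, test_idx, seed = seed)
      ws <- c(ws, w); ls <- c(ls, l); ms <- c(ms, metric)
      if (metric > best$metric) {
        best <- list(spec = list(asv_id = asv_id, w = w, l = l), metric = metric)
      }
      if (task == "classification" && best$metric >= 1) break
    }
    if (task == "classification" && best$metric >= 1) break
  }
  list(spec = best$spec, metric = best$metric,
       grid = data.frame(asv_id = asv_id, w = ws, l = ls, metric = ms))
}

#' Greedy forward screening of candidate ASVs
#'
#' Iterates the candidates in the given order; each ASV is grid-searched for
#' its best (window, lag) on top of the current design matrix and accepted
#' iff its best held-out metric strictly exceeds the incumbent metric (the
#' base-design model's metric at the start). The split is ordered: training
#' on the first `split` share of observations by distance from the source,
#' testing on the remainder, so prediction is always downstream of the
#' training reach. For classification the run stops once accuracy reaches
#' 1.0 (no further strict improvement is possible).
#'
#' @param candidate_order Character vector of ASV ids, in screening order.
#' @param dataset A `river_dataset`.
#' @param task "classification" (status class) or "regression"
#'   (chlorophyll *a*).
#' @param config A [screening_config()].
#' @param seed Integer seed.
#' @param hyperparams Optional override of `config$hyperparams` (used by the
#'   ensemble to inject sampled combinations).
#' @return List of class `screening_model`: `accepted` (specs in inclusion
#'   order), `metric`, `base_metric`, `trajectory`, `hyperparams`, `task`,
#'   `seed`.
#' @export
greedy_screen <- function(candidate_order, dataset, task = "classification",
                          config = screening_config(), seed = 1,
                          hyperparams = NULL) {
  stopifnot(inherits(dataset, "river_dataset"))
  task <- match.arg(task, c("classification", "regression"))
  hp <- if (is.null(hyperparams)) config$hyperparams else hyperparams
  ord <- order_by_flow(dataset$metadata)
  meta <- dataset$metadata[ord, , drop = FALSE]
  series <- hellinger_transform(dataset$abundance)[ord, , drop = FALSE]
  design <- base_design(meta)
  n <- nrow(meta)
  n_train <- floor(config$split * n)
  train_idx <- seq_len(n_train)
  test_idx <- seq(n_train + 1, n)
  response <- if (task == "classification") meta$status_class else meta$chl_a_mg_L
  if (task == "classification") {
    missing_cls <- setdiff(levels(response), unique(as.character(response[train_idx])))
    if (length(missing_cls)) {
      stop("status class(es) ", paste(missing_cls, collapse = ", "),
           " absent from the training split; use a different split or dataset")
    }
  }
  incumbent <- fit_eval_xgb(design, response, task, hp, train_idx, test_idx,
                            seed = seed)
  base_metric <- incumbent
  accepted <- list()
  trajectory <- numeric(0)
  for (asv in candidate_order) {
    if (task == "classification" && incumbent >= 1) break
    gs <- grid_search_asv(asv, design, series, response, task,
                          w_grid = config$w_grid, l_grid = config$l_grid,
                          hyperparams = hp, train_idx = train_idx,
                          test_idx = test_idx, seed = seed)
    if (gs$metric > incumbent + config$tol) {
      design <- lagged_design_matrix(design, series, list(gs$spec))
      incumbent <- gs$metric
      accepted[[length(accepted) + 1]] <- c(gs$spec, metric = gs$metric)
      trajectory <- c(trajectory, gs$metric)
    }
  }
  structure(list(accepted = accepted, metric = incumbent,
                 base_metric = base_metric, trajectory = trajectory,
                 hyperparams = hp, task = task, seed = as.integer(seed)),
            class = "screening_model")
}

#' @export
print.screening_model <- function(x, ...) {
  cat("screening_model (", x$task, "): ", length(x$accepted), " ASVs accepted, ",
      "held-out metric ", sprintf("%.3f", x$metric), "\n", sep = "")
  invisible(x)
}

#' Randomized ensemble of screening runs
#'
#' Runs [greedy_screen()] `n_runs` times, each with a seeded random
#' permutation of the candidate list and boosting hyperparameters sampled
#' from the configured space. The candidate list defaults to the
#' [rf_prefilter()] output truncated to the `config$max_candidates` most
#' important ASVs; each run screens that pool in its own random order.
#' Screening cost grows linearly in the pool size — allocating the budget
#' by prefilter importance is the prefilter's purpose.
#'
#' @param dataset A `river_dataset`.
#' @param task "classification" or "regression".
#' @param n_runs Number of runs (the reference analysis uses 1000).
#' @param config A [screening_config()].
#' @param seed Master seed; the full ensemble is reproducible from it.
#' @param candidates Optional explicit candidate list (skips the prefilter).
#' @return List of class `model_ensemble` with `models`, `candidates`,
#'   `task`, `run_seeds`.
#' @export
ensemble_screen <- function(dataset, task = "classification", n_runs = 1000,
                            config = screening_config(), seed = 1,
                            candidates = NULL) {
  stopifnot(n_runs >= 1)
  set.seed(as.integer(seed))
  if (is.null(candidates)) {
    ord <- order_by_flow(dataset$metadata)
    hmat <- hellinger_transform(dataset$abundance)[ord, , drop = FALSE]
    pf <- rf_prefilter(hmat, dataset$metadata$chl_a_mg_L[ord],
                       seed = sample.int(.Machine$integer.max, 1))
    candidates <- pf$candidates
  }
  if (!length(candidates)) stop("empty candidate list")
  candidates <- utils::head(candidates, config$max_candidates)
  run_seeds <- sample.int(1e9L, n_runs)
  models <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    perm <- sample(candidates)
    hp <- sample_hyperparams(config$space)
    models[[r]] <- greedy_screen(perm, dataset, task = task, config = config,
                                 seed = run_seeds[r], hyperparams = hp)
  }
  structure(list(models = models, candidates = candidates, task = task,
                 run_seeds = run_seeds, seed = as.integer(seed)),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  met <- vapply(x$models, `[[`, numeric(1), "metric")
  cat("model_ensemble (", x$task, "): ", length(x$models), " runs, held-out metric ",
      sprintf("%.3f", min(met)), "-", sprintf("%.3f", max(met)), "\n", sep = "")
  invisible(x)
}
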