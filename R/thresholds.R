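#' Pair up sites along an environmental gradient
#'
#' Expands a dissimilarity matrix into one record per unordered site pair,
#' carrying the two gradient values (stored with `g_lo <= g_hi`) and the
#' Bray-Curtis dissimilarity between the two communities.
#'
#' @param dist A `dist` of community dissimilarities over n sites.
#' @param gradient Per-site gradient values (e.g. chlorophyll a), no missing.
#' @return Data.frame with columns `g_lo`, `g_hi`, `d` and n(n-1)/2 rows.
#' @export
build_pair_set <- function(dist, gradient) {
  n <- attr(dist, "Size")
  if (length(gradient) != n) stop("gradient length does not match the distance matrix")
  if (anyNA(gradient)) stop("gradient has missing values; impute first")
  dm <- as.matrix(dist)
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  gi <- gradient[idx[, 1]]
  gj <- gradient[idx[, 2]]
  data.frame(
    g_lo = pmin(gi, gj),
    g_hi = pmax(gi, gj),
    d = dm[idx]
  )
}

#' Fit a boosted beta-diversity surface over gradient pairs
#'
#' Gradient-boosted regression of pairwise dissimilarity on the two gradient
#' values, with the reported R-squared computed on a seeded random 0.8/0.2
#' pair split (pairs are treated as independent for fitting). Predictions are
#' clipped to [0, 1]. The mean predicted dissimilarity over an evaluation
#' grid spanning the observed gradient range is stored as the baseline
#' beta-diversity.
#'
#' @param pairs Output of [build_pair_set()] (>= 50 pairs).
#' @param n_trees,max_depth,eta,subsample Boosting hyperparameters.
#' @param test_frac Held-out fraction for the R-squared.
#' @param seed Integer seed (split and boosting).
#' @return List of class `surface_model` with the fitted booster, `r_squared`,
#'   `baseline`, and the observed gradient range.
#' @export
fit_surface <- function(pairs, n_trees = 500, max_depth = 3, eta = 0.05,
                        subsample = 0.8, test_frac = 0.2, seed = 1) {
  if (nrow(pairs) < 50) stop("need at least 50 pairs")
  rng <- range(c(pairs$g_lo, pairs$g_hi))
  if (diff(rng) == 0) stop("gradient is single-valued; surface is degenerate")
  set.seed(as.integer(seed))
  n <- nrow(pairs)
  test <- sample.int(n, max(1, round(test_frac * n)))
  X <- as.matrix(pairs[, c("g_lo", "g_hi")])
  y <- pairs$d
  dtrain <- xgboost::xgb.DMatrix(X[-test, , drop = FALSE], label = y[-test])
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = max_depth,
                  eta = eta, subsample = subsample, nthread = 1,
                  seed = as.integer(seed)),
    data = dtrain, nrounds = n_trees, verbose = 0
  )
  pred <- pmin(1, pmax(0, stats::predict(booster, X[test, , drop = FALSE])))
  ss_tot <- sum((y[test] - mean(y[test]))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum((y[test] - pred)^2) / ss_tot
  grid <- seq(rng[1], rng[2], length.out = 60)
  gp <- expand.grid(g_lo = grid, g_hi = grid)
  gp <- gp[gp$g_lo <= gp$g_hi, ]
  baseline <- mean(pmin(1, pmax(0, stats::predict(booster, as.matrix(gp)))))
  structure(
    list(booster = booster, r_squared = r2, baseline = baseline,
         gradient_range = rng, n_pairs = n),
    class = "surface_model"
  )
}

#' Predict the surface at gradient pairs
#' @param model A `surface_model`.
#' @param g_lo,g_hi Gradient values; internally reordered so g_lo <= g_hi.
#' @return Predicted dissimilarities clipped to [0, 1].
#' @export
predict_surface <- function(model, g_lo, g_hi) {
  X <- cbind(g_lo = pmin(g_lo, g_hi), g_hi = pmax(g_lo, g_hi))
  pmin(1, pmax(0, stats::predict(model$booster, X)))
}

#' Detect gradient thresholds on the beta-diversity surface
#'
#' For each grid value c, the spanning score S(c) is the mean predicted
#' dissimilarity over pairs (a, b) with `a <= c - band` and `b >= c + band`:
#' how different communities on the two sides of c are. Thresholds (ridges)
#' are strict local maxima of the discrete derivative of S that exceed the
#' baseline rate of change (the mean absolute derivative); maximal runs where
#' S sits below the model baseline and the derivative is below the baseline
#' rate are reported as homogeneous segments (valleys).
#'
#' @param model A `surface_model`.
#' @param grid Evenly spaced gradient values covering the observed range.
#' @param band Half-gap around c (default one grid step); must be smaller
#'   than half the gradient range.
#' @return List with `thresholds` (gradient values), `segments` (data.frame
#'   of homogeneous intervals), and `score` (data.frame of c, S(c)).
#' @export
detect_thresholds <- function(model, grid = NULL, band = NULL) {
  rng <- model$gradient_range
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 61)
  grid <- sort(grid)
  step <- stats::median(diff(grid))
  if (is.null(band)) band <- step
  if (band >= diff(rng) / 2) stop("band must be smaller than half the gradient range")
  # predicted surface on the grid (upper triangle once)
  gp <- expand.grid(a = grid, b = grid)
  gp <- gp[gp$a <= gp$b, ]
  gp$pred <- predict_surface(model, gp$a, gp$b)
  S <- vapply(grid, function(cc) {
    sel <- gp$a <= cc - band & gp$b >= cc + band
    if (!any(sel)) NA_real_ else mean(gp$pred[sel])
  }, numeric(1))
  ok <- which(is.finite(S))
  g2 <- grid[ok]
  S2 <- S[ok]
  if (length(S2) < 4) {
    return(list(thresholds = numeric(0),
                segments = data.frame(lo = numeric(0), hi = numeric(0)),
                score = data.frame(c = g2, S = S2)))
  }
  dS <- diff(S2) / diff(g2)                   # derivative at interval midpoints
  mid <- (g2[-1] + g2[-length(g2)]) / 2
  base_rate <- mean(abs(dS))
  # candidate ridges exceed the baseline rate of change with prominence
  # comparable to the strongest ridge (rules out the background drift that a
  # global spanning average carries on fine grids)
  floor_rate <- max(base_rate, 0.5 * max(dS))
  cand <- which(dS > floor_rate & dS > 0)
  # tree surfaces are piecewise constant, so one composition shift can split
  # its rise over nearby intervals: merge candidates closer than one
  # smoothing width and keep each cluster's downstream edge (the point where
  # the rise saturates), then shift back by the band: S(c) compares sites
  # strictly below c - band with sites above c + band, so saturation occurs
  # one band below the true change point
  thresholds <- numeric(0)
  if (length(cand)) {
    gap <- 2 * band + stats::median(diff(grid))
    cluster <- cumsum(c(1, diff(mid[cand]) > gap))
    edge <- vapply(split(cand, cluster), max, numeric(1))
    thresholds <- mid[edge] + band
  }
  # valleys: flat (below baseline level and baseline rate) maximal runs
  flat <- abs(dS) < base_rate &
    (S2[-1] + S2[-length(S2)]) / 2 < model$baseline
  segments <- run_segments(mid, flat)
  list(thresholds = thresholds, segments = segments,
       score = data.frame(c = g2, S = S2))
}

run_segments <- function(x, flag) {
  if (!any(flag)) return(data.frame(lo = numeric(0), hi = numeric(0)))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(lo = x[starts[keep]], hi = x[ends[keep]])
}
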