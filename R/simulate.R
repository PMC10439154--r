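#' River sampling design for the synthetic generator
#'
#' Describes the spatial layout of a longitudinally sampled river: ordered
#' stations with strictly decreasing distance to the river mouth, three
#' bank-parallel transects (left, center, right), smooth environmental
#' gradients with additive noise, and cutpoints mapping latent saprobity to
#' discrete biological status classes.
#'
#' @param n_stations Number of stations per transect (>= 10).
#' @param transects Character vector of transect labels.
#' @param river_length_km Distance to mouth of the most upstream station, km.
#' @param gradient_params Named list of `c(start, end, sd)` triples, one per
#'   environmental variable: linear trend from the most upstream station
#'   (`start`) to the mouth (`end`) plus iid Gaussian noise with sd `sd`.
#' @param class_cutpoints Quantile probabilities in (0,1) at which the latent
#'   saprobity is cut into ordered status classes (k cutpoints give k+1
#'   classes).
#'
#' @return A list of class `river_design`.
#' @export
river_design <- function(n_stations = 60,
                         transects = c("left", "center", "right"),
                         river_length_km = 2580,
                         gradient_params = default_gradients(),
                         class_cutpoints = c(1 / 3, 2 / 3)) {
  stopifnot(n_stations >= 10, length(transects) >= 1, river_length_km > 0)
  if (any(class_cutpoints <= 0) || any(class_cutpoints >= 1) ||
      is.unsorted(class_cutpoints, strictly = TRUE)) {
    stop("class_cutpoints must be strictly increasing quantile probabilities in (0,1)")
  }
  # station 1 is the most upstream (largest distance to mouth)
  dist_km <- river_length_km * (n_stations:1) / n_stations
  structure(
    list(
      n_stations = as.integer(n_stations),
      transects = transects,
      distance_to_mouth = dist_km,
      gradient_params = gradient_params,
      class_cutpoints = class_cutpoints
    ),
    class = "river_design"
  )
}

#' Default environmental gradients
#'
#' Trends loosely follow a large lowland river from headwaters to mouth:
#' cooling-to-warming temperature, slightly falling pH and conductivity,
#' nutrient dilution downstream, rising chlorophyll *a* (the eutrophication
#' proxy), and log10(x+1)-scale fecal indicators. Units are carried in the
#' column names.
#'
#' @return Named list of `c(start, end, sd)` triples.
#' @export
default_gradients <- function() {
  list(
    pH                  = c(start = 8.4, end = 8.0, sd = 0.05),
    conductivity_uS_cm  = c(start = 450, end = 330, sd = 10),
    water_temp_C        = c(start = 12,  end = 22,  sd = 0.6),
    Ntot_mg_L           = c(start = 2.6, end = 1.2, sd = 0.08),
    chl_a_mg_L          = c(start = 1.4, end = 3.0, sd = 0.25),
    DOC_mg_L            = c(start = 3.6, end = 2.4, sd = 0.12),
    log_total_coliforms = c(start = 4.2, end = 3.1, sd = 0.15),
    log_ecoli           = c(start = 3.4, end = 2.2, sd = 0.15)
  )
}

#' Planted indicator signal
#'
#' Defines the indicator ASVs the generator plants into the community and the
#' rule by which they drive the biological status class. Each redundancy
#' group holds one parent indicator plus near-identical clones (multiplicative
#' log-normal jitter), all assigned to the same genus. The parent follows
#' trigger-taxon dynamics along each transect: a two-state Markov chain in
#' which the taxon is below detection in the low state and a stable small
#' share of the community in the high state. The latent response is the
#' weighted sum of thresholded, windowed-standardized, lagged indicator
#' series plus Gaussian noise.
#'
#' @param n_groups Number of redundancy groups (complementary indicators).
#' @param clones_per_group Total members per group including the parent.
#' @param true_lag Integer lag (upstream sites) per group, recycled.
#' @param true_window Integer window per group (1 = raw lagged value).
#' @param effect_weights Contribution of each group's thresholded series.
#' @param response_cutpoints Cutpoints on the latent response separating
#'   status classes. The default single cutpoint at 0.5 yields a binary
#'   status (compliant / degraded: degraded as soon as any indicator group
#'   is in its high state); pass `seq_len(n_groups) - 0.5` for one class
#'   per number of elevated groups.
#' @param noise_sd Gaussian sd added to the latent response (0 = the class is
#'   an exact function of the planted series).
#' @param state_prob_high Stationary probability of the high state. The
#'   default 0.3 (elevated at roughly a third of sites) balances the binary
#'   status classes under the OR-type response rule and gives each indicator
#'   a strong marginal signal.
#' @param state_persistence Lag-1 autocorrelation of the state chain
#'   (0 = iid states along the transect).
#' @param state_logfc Log fold change between the low and high state.
#' @param clone_jitter_sd Log-normal sd of the clone multiplicative jitter.
#'
#' @return A list of class `planted_signal`.
#' @export
planted_signal <- function(n_groups = 2,
                           clones_per_group = 3,
                           true_lag = c(1, 2),
                           true_window = 1,
                           effect_weights = 1,
                           response_cutpoints = NULL,
                           noise_sd = 0,
                           state_prob_high = 0.3,
                           state_persistence = 0.35,
                           state_logfc = 2.4,
                           clone_jitter_sd = 0.05) {
  stopifnot(n_groups >= 1, clones_per_group >= 1)
  true_lag <- as.integer(rep_len(true_lag, n_groups))
  true_window <- as.integer(rep_len(true_window, n_groups))
  effect_weights <- rep_len(effect_weights, n_groups)
  if (any(true_lag < 0)) stop("true_lag must be >= 0")
  if (any(true_window < 1)) stop("true_window must be >= 1")
  if (is.null(response_cutpoints)) {
    response_cutpoints <- 0.5
  }
  groups <- lapply(seq_len(n_groups), function(g) {
    ids <- sprintf("ASV_ind%d_%s", g, letters[seq_len(clones_per_group)])
    list(ids = ids, parent = ids[1], lag = true_lag[g], window = true_window[g],
         weight = effect_weights[g])
  })
  structure(
    list(
      groups = groups,
      indicator_ids = unlist(lapply(groups, `[[`, "ids")),
      redundancy_groups = lapply(groups, `[[`, "ids"),
      true_lag = true_lag,
      true_window = true_window,
      effect_weights = effect_weights,
      response_cutpoints = response_cutpoints,
      noise_sd = noise_sd,
      state_prob_high = state_prob_high,
      state_persistence = state_persistence,
      state_logfc = state_logfc,
      clone_jitter_sd = clone_jitter_sd
    ),
    class = "planted_signal"
  )
}

#' Simulate station metadata along the river
#'
#' Generates one metadata row per (station, transect) with environmental
#' variables following the design's linear trends plus Gaussian noise. A
#' latent saprobity — the standardized sum of the nutrient and fecal-indicator
#' values (the variables that track organic pollution) — is cut at the
#' design's quantile cutpoints into an ordered `status_class`. When the
#' community is simulated as well, [simulate_dataset()] replaces this
#' trend-derived class by the indicator-driven one.
#'
#' @param design A [river_design()].
#' @param seed Integer seed; identical (design, seed) give identical output.
#' @return A data.frame of sample metadata ordered upstream to downstream
#'   within each transect.
#' @export
simulate_river <- function(design, seed) {
  stopifnot(inherits(design, "river_design"))
  d <- design$distance_to_mouth
  if (any(d <= 0) || any(diff(d) >= 0)) {
    stop("distance_to_mouth must be strictly positive and strictly decreasing")
  }
  n <- design$n_stations
  set.seed(as.integer(seed))
  rows <- list()
  for (tr in design$transects) {
    env <- lapply(names(design$gradient_params), function(v) {
      p <- design$gradient_params[[v]]
      x <- (seq_len(n) - 1) / (n - 1)
      # chlorophyll a fluctuates along large rivers (impoundments, tributary
      # inputs) rather than trending monotonically; its trend sweeps the
      # start..end span periodically so downstream values stay within the
      # range seen upstream
      if (v == "chl_a_mg_L") {
        mid <- (p[["start"]] + p[["end"]]) / 2
        half <- (p[["end"]] - p[["start"]]) / 2
        trend <- mid + half * sin(3 * pi * x - 1)
      } else {
        trend <- p[["start"]] + (p[["end"]] - p[["start"]]) * x
      }
      trend + stats::rnorm(n, 0, p[["sd"]])
    })
    names(env) <- names(design$gradient_params)
    rows[[tr]] <- data.frame(
      sample_id = sprintf("%s_%02d", toupper(substr(tr, 1, 1)), seq_len(n)),
      transect = tr,
      station = seq_len(n),
      distance_to_mouth_km = d,
      as.data.frame(env),
      stringsAsFactors = FALSE
    )
  }
  meta <- do.call(rbind, rows)
  rownames(meta) <- NULL
  latent <- as.numeric(scale(meta$Ntot_mg_L)) +
    as.numeric(scale(meta$log_ecoli)) +
    as.numeric(scale(meta$log_total_coliforms))
  meta$latent_saprobity <- latent
  cuts <- stats::quantile(latent, probs = design$class_cutpoints, type = 7)
  meta$status_class <- cut_status(latent, cuts)
  meta
}

cut_status <- function(latent, cutpoints) {
  k <- length(cutpoints) + 1
  cls <- findInterval(latent, cutpoints, left.open = TRUE) + 1L
  factor(paste0("class", cls), levels = paste0("class", seq_len(k)), ordered = TRUE)
}

#' Simulate the ASV community with planted lagged indicators
#'
#' Background taxa get log-normal latent intensities with a per-taxon linear
#' longitudinal trend and station-autocorrelated AR(1) noise; counts are drawn
#' by closing the intensities to `library_size` with a multinomial draw per
#' sample. Indicator parents follow two-state Markov series; clones are the
#' parent intensity times log-normal jitter. The planted indicators'
#' windowed-standardized lagged relative-abundance series (the exact feature
#' construction the screening module searches over) are thresholded at the
#' midpoint between their state levels and combined into the latent response
#' that assigns the status class.
#'
#' @param design A [river_design()].
#' @param signal A [planted_signal()].
#' @param n_noise_taxa Number of background taxa.
#' @param library_size Counts per sample after compositional closure.
#' @param seed Integer seed.
#' @param ar_rho AR(1) autocorrelation of background log intensities.
#' @return A list with elements `counts` (samples x taxa integer matrix,
#'   ordered as [simulate_river()] metadata), `taxonomy` (data.frame),
#'   `status_class` (ordered factor driven by the planted indicators),
#'   `latent_response`, and `features` (the planted lagged series).
#' @export
simulate_community <- function(design, signal, n_noise_taxa = 200,
                               library_size = 50000, seed = 1, ar_rho = 0.6) {
  stopifnot(inherits(design, "river_design"), inherits(signal, "planted_signal"))
  n <- design$n_stations
  trs <- design$transects
  n_samples <- n * length(trs)
  noise_ids <- sprintf("ASV_noise_%03d", seq_len(n_noise_taxa))
  if (any(signal$indicator_ids %in% noise_ids)) {
    stop("indicator ids must be disjoint from noise taxon ids")
  }
  taxa <- c(signal$indicator_ids, noise_ids)
  if (library_size < length(taxa)) {
    stop("library_size must be at least the number of taxa")
  }
  if (any(signal$true_lag >= n)) stop("true_lag must be smaller than n_stations")

  set.seed(as.integer(seed))
  # per-taxon global parameters (shared across transects -> coherent taxa)
  base <- stats::rnorm(n_noise_taxa, 0, 1.5)
  slope <- stats::rnorm(n_noise_taxa, 0, 1.5)

  counts <- matrix(0L, nrow = n_samples, ncol = length(taxa),
                   dimnames = list(NULL, taxa))
  sample_ids <- character(n_samples)
  states <- matrix(0L, nrow = n_samples, ncol = length(signal$groups))
  row0 <- 0
  for (tr in trs) {
    lam <- matrix(0, nrow = n, ncol = length(taxa), dimnames = list(NULL, taxa))
    # background: lognormal latent with AR(1) station autocorrelation
    for (j in seq_len(n_noise_taxa)) {
      ar <- as.numeric(stats::arima.sim(list(ar = ar_rho), n = n,
                                        sd = 0.5 * sqrt(1 - ar_rho^2)))
      lam[, noise_ids[j]] <- exp(base[j] + slope[j] * (seq_len(n) - 1) / (n - 1) + ar)
    }
    # close the background to a constant total load per station: total
    # bacterial load per volume is roughly stable along the river and only
    # the composition shifts; this also keeps the planted indicators'
    # relative abundances pinned to their state levels
    bg <- lam[, noise_ids, drop = FALSE]
    lam[, noise_ids] <- bg / rowSums(bg) * 600
    # indicators: persistent two-state parents + jittered clones
    for (g in seq_along(signal$groups)) {
      grp <- signal$groups[[g]]
      # two-state Markov chain with stationary P(high) and lag-1
      # autocorrelation state_persistence
      pi1 <- signal$state_prob_high
      rho <- signal$state_persistence
      st <- integer(n)
      st[1] <- stats::rbinom(1, 1, pi1)
      u <- stats::runif(n - 1)
      for (i in 2:n) {
        p_hi <- rho * st[i - 1] + (1 - rho) * pi1
        st[i] <- as.integer(u[i - 1] < p_hi)
      }
      states[row0 + seq_len(n), g] <- st
      # trigger-taxon dynamics: below detection in the low state, a small
      # share of the total load in the high state (so one group's state does
      # not move another's relative abundance), with a mild downstream drift
      # mirroring the longitudinal succession of the background taxa
      parent <- st * exp(0.8 + signal$state_logfc +
                           0.35 * (seq_len(n) - 1) / (n - 1) +
                           stats::rnorm(n, 0, 0.05))
      lam[, grp$ids[1]] <- parent
      for (cl in grp$ids[-1]) {
        lam[, cl] <- parent * exp(stats::rnorm(n, 0, signal$clone_jitter_sd))
      }
    }
    for (i in seq_len(n)) {
      counts[row0 + i, ] <- stats::rmultinom(1, size = library_size,
                                             prob = lam[i, ] / sum(lam[i, ]))
    }
    sample_ids[row0 + seq_len(n)] <- sprintf("%s_%02d", toupper(substr(tr, 1, 1)),
                                             seq_len(n))
    row0 <- row0 + n
  }
  rownames(counts) <- sample_ids

  rel <- counts / rowSums(counts)
  transect_of <- rep(trs, each = n)
  feats <- matrix(NA_real_, nrow = n_samples, ncol = length(signal$groups))
  thresholds <- numeric(length(signal$groups))
  contrib <- matrix(0, nrow = n_samples, ncol = length(signal$groups))
  for (g in seq_along(signal$groups)) {
    grp <- signal$groups[[g]]
    for (tr in trs) {
      idx <- which(transect_of == tr)
      feats[idx, g] <- lag_window_series(rel[idx, grp$parent],
                                         w = grp$window, l = grp$lag)
    }
    # threshold at the midpoint between the state-level means of the realized
    # lagged series (lagged state = state at the source site, clamped upstream)
    src_state <- unlist(lapply(trs, function(tr) {
      idx <- which(transect_of == tr)
      st <- states[idx, g]
      st[pmax(seq_along(idx) - grp$lag, 1L)]
    }))
    lo <- mean(feats[src_state == 0L, g])
    hi <- mean(feats[src_state == 1L, g])
    if (!is.finite(lo) || !is.finite(hi)) {
      thresholds[g] <- stats::median(feats[, g])
    } else {
      thresholds[g] <- (lo + hi) / 2
    }
    contrib[, g] <- grp$weight * as.numeric(feats[, g] > thresholds[g])
  }
  latent <- rowSums(contrib) + stats::rnorm(n_samples, 0, signal$noise_sd)
  status <- cut_status(latent, signal$response_cutpoints)
  # chlorophyll a responds locally (lag 0) to the same elevated states: the
  # algal response to the conditions that favor the trigger taxa at the site
  # itself, while the biological status integrates them with a spatial lag
  chl_amp <- 1.6 / sqrt(seq_along(signal$groups))
  chl_effect <- as.numeric(states %*% chl_amp)

  list(
    counts = counts,
    taxonomy = synth_taxonomy(signal, noise_ids),
    status_class = status,
    latent_response = latent,
    chl_effect = chl_effect,
    features = feats,
    feature_thresholds = thresholds
  )
}

# windowed standardization + lag of a single within-transect series,
# identical to the engine used by lagged_design_matrix (w = 1 -> raw lagged
# value). Warm-up uses only the history actually available upstream: the
# source index is clamped at the transect start and the window truncated to
# the sites before it, so no engineered value ever depends on a downstream
# site; a site whose truncated window has a single member gets the neutral
# standardized value 0. Vectorized via cumulative sums: the screening grid
# search calls this tens of thousands of times.
lag_window_series <- function(x, w, l) {
  n <- length(x)
  if (l >= n) stop("lag must be smaller than the transect length")
  src <- pmax(seq_len(n) - l, 1L)     # clamp at the transect start
  if (w == 1) return(x[src])
  w_eff <- pmin(w, src)               # truncated warm-up window
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  mu <- (cs[src + 1] - cs[src - w_eff + 1]) / w_eff
  ss <- pmax((cs2[src + 1] - cs2[src - w_eff + 1]) - w_eff * mu^2, 0)
  sdv <- sqrt(ss / pmax(w_eff - 1, 1))
  # rounding collapses cancellation noise from the cumulative sums, which
  # would otherwise create spurious sub-ulp splits for tree learners
  out <- round(ifelse(sdv < 1e-12, 0, (x[src] - mu) / sdv), 8)
  out[w_eff == 1] <- 0
  out
}

synth_taxonomy <- function(signal, noise_ids) {
  phyla <- c("Proteobacteria", "Bacteroidota", "Actinobacteriota",
             "Verrucomicrobiota", "Cyanobacteria", "Planctomycetota")
  n_noise <- length(noise_ids)
  # hierarchically consistent labels (each label embeds its full path) with
  # phyla interleaved so even small pools span several phyla
  g <- ((seq_len(n_noise) - 1) %% 48) + 1
  p <- ((g - 1) %% length(phyla)) + 1
  cl <- ((g - 1) %/% 6) %% 2 + 1
  o <- ((g - 1) %/% 12) %% 2 + 1
  f <- ((g - 1) %/% 24) %% 2 + 1
  noise_tax <- data.frame(
    asv_id = noise_ids,
    Kingdom = "Bacteria",
    Phylum = phyla[p],
    Class = sprintf("Class_%d_%d", p, cl),
    Order = sprintf("Order_%d_%d_%d", p, cl, o),
    Family = sprintf("Family_%d_%d_%d_%d", p, cl, o, f),
    Genus = sprintf("Genus_%02d", g),
    stringsAsFactors = FALSE
  )
  ind_tax <- do.call(rbind, lapply(seq_along(signal$groups), function(g) {
    ids <- signal$groups[[g]]$ids
    data.frame(
      asv_id = ids,
      Kingdom = "Bacteria",
      Phylum = phyla[((g - 1) %% length(phyla)) + 1],
      Class = sprintf("Class_ind%d", g),
      Order = sprintf("Order_ind%d", g),
      Family = sprintf("Family_ind%d", g),
      Genus = sprintf("Genus_ind%d", g),
      stringsAsFactors = FALSE
    )
  }))
  tax <- rbind(ind_tax, noise_tax)
  rownames(tax) <- NULL
  tax
}

#' Simulate a complete synthetic river dataset
#'
#' Runs [simulate_river()] and [simulate_community()] under one master seed
#' and assembles a validated dataset in which the status class is the
#' indicator-driven one.
#'
#' @inheritParams simulate_community
#' @return An object of class `river_dataset`: list with `abundance`
#'   (samples x taxa counts), `taxonomy`, and `metadata`.
#' @export
simulate_dataset <- function(design = river_design(), signal = planted_signal(),
                             n_noise_taxa = 200, library_size = 50000, seed = 1) {
  meta <- simulate_river(design, seed = seed)
  com <- simulate_community(design, signal, n_noise_taxa = n_noise_taxa,
                            library_size = library_size, seed = seed + 1L)
  stopifnot(identical(meta$sample_id, rownames(com$counts)))
  meta$status_class <- com$status_class
  meta$latent_response <- com$latent_response
  meta$chl_a_mg_L <- meta$chl_a_mg_L + com$chl_effect
  new_river_dataset(com$counts, com$taxonomy, meta)
}

#' Simulate a community with one abrupt composition change along a gradient
#'
#' Sites are assigned evenly spaced gradient values; sites below the change
#' point draw counts from one community profile, sites at or above it from a
#' second, unrelated profile, with per-site log-normal intensity jitter.
#' Used to test threshold localization on the beta-diversity surface.
#'
#' @param n_sites Number of sites.
#' @param gradient_range Numeric length-2, range of the gradient.
#' @param change_point Gradient value at which the composition shifts.
#' @param n_taxa Taxa per profile pool.
#' @param library_size Counts per site.
#' @param jitter_sd Log-normal per-site intensity jitter sd.
#' @param seed Integer seed.
#' @return List with `counts` (sites x taxa) and `gradient`.
#' @export
simulate_step_community <- function(n_sites = 120, gradient_range = c(0, 6),
                                    change_point = 3, n_taxa = 40,
                                    library_size = 5000, jitter_sd = 0.15,
                                    seed = 1) {
  stopifnot(n_sites >= 10, change_point > gradient_range[1],
            change_point < gradient_range[2])
  set.seed(as.integer(seed))
  g <- seq(gradient_range[1], gradient_range[2], length.out = n_sites)
  prof_a <- exp(stats::rnorm(n_taxa, 0, 1.5))
  prof_b <- exp(stats::rnorm(n_taxa, 0, 1.5))
  counts <- t(vapply(seq_len(n_sites), function(i) {
    prof <- if (g[i] < change_point) prof_a else prof_b
    lam <- prof * exp(stats::rnorm(n_taxa, 0, jitter_sd))
    as.integer(stats::rmultinom(1, library_size, lam / sum(lam)))
  }, integer(n_taxa)))
  colnames(counts) <- sprintf("ASV_%03d", seq_len(n_taxa))
  rownames(counts) <- sprintf("S_%03d", seq_len(n_sites))
  list(counts = counts, gradient = g)
}

#' Write a dataset to tab-delimited fixture files
#'
#' Writes the abundance table (rows = samples), taxonomy and metadata as
#' UTF-8, tab-delimited files with header rows, readable by [load_dataset()].
#'
#' @param dataset A `river_dataset`.
#' @param directory Output directory (created if absent).
#' @return Named character vector of the three file paths.
#' @export
write_fixture <- function(dataset, directory) {
  stopifnot(inherits(dataset, "river_dataset"))
  if (nrow(dataset$abundance) == 0 || ncol(dataset$abundance) == 0) {
    stop("cannot write an empty dataset")
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    asv = file.path(directory, "asv_table.tsv"),
    taxonomy = file.path(directory, "taxonomy.tsv"),
    metadata = file.path(directory, "metadata.tsv")
  )
  ab <- data.frame(sample_id = rownames(dataset$abundance),
                   dataset$abundance, check.names = FALSE)
  utils::write.table(ab, paths[["asv"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(dataset$taxonomy, paths[["taxonomy"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(dataset$metadata, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  paths
}
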