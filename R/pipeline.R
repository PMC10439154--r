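#' Run the full bioindicator pipeline from a configuration
#'
#' Orchestrates the analysis stages in dependency order from a single
#' configuration (an R list or a YAML file path): data loading or synthetic
#' simulation, prevalence/CV candidate screening, dbRDA ordination,
#' beta-diversity threshold surface, spatio-temporal screening ensemble, and
#' network analysis. Each stage writes plain-text outputs under `out_dir`
#' and is logged in a manifest (stage, seed, outputs, md5 digests, wall
#' time); identical configurations and seeds give identical digests.
#'
#' Configuration schema: `seed` (required), `out_dir` (required), either
#' `input: list(asv, taxonomy, metadata)` paths or `synthetic: list(...)`
#' arguments for [simulate_dataset()]; `tasks` — subset of
#' `c("prevalence", "ordination", "thresholds", "screening", "networks")`;
#' optional stage blocks `prevalence: list(rank, n_top)`,
#' `ordination: list(rank, alpha, n_perm)`, `thresholds: list(grid_step)`,
#' `screening: list(task, n_runs, max_candidates)`,
#' `networks: list(percentile)`.
#'
#' @param config List or path to a YAML file.
#' @return Invisibly, the manifest data.frame (also written as JSON).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  tasks <- config$tasks %||% c("prevalence", "ordination", "thresholds",
                               "screening", "networks")
  manifest <- list()
  log_stage <- function(stage, outputs, t0) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, seed = seed, output = outputs,
      digest = unname(tools::md5sum(outputs)),
      wall_time_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    )
  }

  t0 <- Sys.time()
  if (!is.null(config$input)) {
    ds <- load_dataset(config$input$asv, config$input$taxonomy,
                       config$input$metadata)
  } else {
    s <- config$synthetic %||% list()
    ds <- simulate_dataset(
      design = river_design(n_stations = s$n_stations %||% 60),
      signal = planted_signal(
        n_groups = s$n_groups %||% 2,
        clones_per_group = s$clones_per_group %||% 3,
        true_lag = unlist(s$true_lag %||% c(1, 2)),
        noise_sd = s$noise_sd %||% 0
      ),
      n_noise_taxa = s$n_noise_taxa %||% 200,
      library_size = s$library_size %||% 50000,
      seed = s$seed %||% seed
    )
    paths <- write_fixture(ds, file.path(out_dir, "synthetic"))
    log_stage("simulate", unname(paths), t0)
  }

  ens <- NULL
  for (stage in tasks) {
    t0 <- Sys.time()
    switch(stage,
      prevalence = {
        prm <- config$prevalence %||% list()
        rank <- prm$rank %||% "Genus"
        agg <- aggregate_taxa(ds$abundance, ds$taxonomy, rank)
        sc <- select_candidates(prevalence_cv(agg), n_top = prm$n_top %||% 15)
        f <- file.path(out_dir, "prevalence_screen.tsv")
        utils::write.table(sc, f, sep = "\t", quote = FALSE, row.names = FALSE)
        log_stage("prevalence", f, t0)
      },
      ordination = {
        prm <- config$ordination %||% list()
        rank <- prm$rank %||% "Phylum"
        agg <- aggregate_taxa(ds$abundance, ds$taxonomy, rank)
        d <- bray_curtis(hellinger_transform(agg))
        env <- ds$metadata[vapply(ds$metadata, is.numeric, logical(1))]
        env <- env[setdiff(names(env), c("station", "latent_saprobity",
                                         "latent_response"))]
        env <- impute_pmm(env, seed = seed)
        vars <- vif_filter(env, threshold = prm$vif_threshold %||% 5)
        fs <- forward_select(d, env[vars], alpha = prm$alpha %||% 0.05,
                             n_perm = prm$n_perm %||% 199, seed = seed)
        outs <- file.path(out_dir, c("forward_selection.tsv", "dbrda_scores.tsv",
                                     "dbrda_eigenvalues.tsv"))
        utils::write.table(fs, outs[1], sep = "\t", quote = FALSE, row.names = FALSE)
        if (nrow(fs) >= 1) {
          db <- dbrda_fit(d, env[fs$variable], n_perm = prm$n_perm %||% 199,
                          seed = seed)
          utils::write.table(as.data.frame(db$site_scores), outs[2], sep = "\t",
                             quote = FALSE)
          ev <- data.frame(axis = c(names(db$eig_constrained),
                                    names(db$eig_unconstrained)),
                           eigenvalue = c(db$eig_constrained, db$eig_unconstrained),
                           constrained = rep(c(TRUE, FALSE),
                                             c(length(db$eig_constrained),
                                               length(db$eig_unconstrained))))
          utils::write.table(ev, outs[3], sep = "\t", quote = FALSE, row.names = FALSE)
        } else {
          outs <- outs[1]
        }
        log_stage("ordination", outs, t0)
      },
      thresholds = {
        prm <- config$thresholds %||% list()
        d <- bray_curtis(hellinger_transform(ds$abundance))
        meta <- ds$metadata
        pairs <- build_pair_set(d, meta$chl_a_mg_L)
        sm <- fit_surface(pairs, seed = seed)
        step <- prm$grid_step %||% 0.1
        grid <- seq(sm$gradient_range[1], sm$gradient_range[2], by = step)
        th <- detect_thresholds(sm, grid = grid)
        outs <- file.path(out_dir, c("threshold_pairs.tsv", "threshold_score.tsv",
                                     "thresholds.tsv"))
        utils::write.table(pairs, outs[1], sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(th$score, outs[2], sep = "\t", quote = FALSE,
                           row.names = FALSE)
        utils::write.table(
          data.frame(threshold = th$thresholds, r_squared = sm$r_squared,
                     baseline = sm$baseline),
          outs[3], sep = "\t", quote = FALSE, row.names = FALSE)
        log_stage("thresholds", outs, t0)
      },
      screening = {
        prm <- config$screening %||% list()
        cfg <- screening_config(
          max_candidates = prm$max_candidates %||% 15
        )
        ens <- ensemble_screen(ds, task = prm$task %||% "classification",
                               n_runs = prm$n_runs %||% 100, config = cfg,
                               seed = seed)
        f <- file.path(out_dir, "screening_runs.jsonl")
        con <- file(f, open = "w")
        for (m in ens$models) {
          writeLines(jsonlite::toJSON(list(
            seed = m$seed, metric = m$metric, task = m$task,
            hyperparams = m$hyperparams,
            accepted = lapply(m$accepted, function(a)
              list(asv_id = a$asv_id, w = a$w, l = a$l))
          ), auto_unbox = TRUE), con)
        }
        close(con)
        log_stage("screening", f, t0)
      },
      networks = {
        if (is.null(ens)) stop("networks stage requires the screening stage output")
        prm <- config$networks %||% list()
        best <- select_best_models(ens)
        if (!length(best)) stop("no retained models; networks stage refused")
        pa <- presence_absence(best)
        pct <- prm$percentile %||% 95
        outs <- file.path(out_dir, c("cooccurrence.graphml", "coexclusion.graphml",
                                     "dendrogram.nwk", "minimal_models.tsv"))
        co <- build_cooccurrence(pa, percentile = pct, taxonomy = ds$taxonomy)
        igraph::write_graph(co, outs[1], format = "graphml")
        written <- outs[c(1, 4)]
        if (length(percentile_filter(colSums(pa), pct)) >= 2) {
          cx <- build_coexclusion(pa, percentile = pct, taxonomy = ds$taxonomy)
          igraph::write_graph(cx, outs[2], format = "graphml")
          written <- c(written, outs[2])
        }
        if (ncol(pa) >= 2) {
          dn <- taxonomy_dendrogram(colnames(pa), ds$taxonomy,
                                    occurrence = colSums(pa))
          writeLines(dn$newick, outs[3])
          written <- c(written, outs[3])
        }
        mm <- minimal_models(best)
        utils::write.table(
          data.frame(model = seq_along(mm$sets), size = mm$size,
                     asvs = vapply(mm$sets, paste, character(1), collapse = ",")),
          outs[4], sep = "\t", quote = FALSE, row.names = FALSE)
        log_stage("networks", sort(written), t0)
      },
      stop("unknown stage: ", stage)
    )
  }
  manifest <- do.call(rbind, manifest)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

validate_config <- function(config) {
  if (is.null(config$seed)) stop("config requires a seed")
  if (is.null(config$out_dir)) stop("config requires an out_dir")
  if (is.null(config$input) && is.null(config$synthetic)) {
    stop("config requires either an input block or a synthetic block")
  }
  if (!is.null(config$input)) {
    need <- c("asv", "taxonomy", "metadata")
    miss <- setdiff(need, names(config$input))
    if (length(miss)) stop("input block lacks: ", paste(miss, collapse = ", "))
    for (p in unlist(config$input[need])) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
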