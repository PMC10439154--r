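#' Retain the best screening models of an ensemble
#'
#' Classification: all models with perfect (100%) held-out accuracy.
#' Regression: the single model with the highest held-out R-squared (ties
#' resolved to the lowest run seed).
#'
#' @param ensemble A `model_ensemble`.
#' @param task Defaults to the ensemble's task.
#' @return List of retained `screening_model`s (possibly empty for
#'   classification, with a warning).
#' @export
select_best_models <- function(ensemble, task = ensemble$task) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  metrics <- vapply(ensemble$models, `[[`, numeric(1), "metric")
  if (task == "classification") {
    keep <- which(metrics >= 1 - 1e-12)
    if (!length(keep)) warning("no model reached 100% held-out accuracy")
    ensemble$models[keep]
  } else {
    best <- max(metrics)
    cand <- which(metrics == best)
    seeds <- vapply(ensemble$models[cand], `[[`, integer(1), "seed")
    ensemble$models[cand[which.min(seeds)]]
  }
}

#' Presence/absence table of retained models
#'
#' Binary matrix with one row per retained model and one column per ASV ever
#' accepted; models with empty accepted sets are excluded. Column sums are
#' the ASV occurrence counts that feed the network analysis.
#'
#' @param models List of `screening_model`s.
#' @return Binary matrix (models x ASVs).
#' @export
presence_absence <- function(models) {
  sets <- lapply(models, function(m) {
    vapply(m$accepted, function(a) a$asv_id, character(1))
  })
  keep <- lengths(sets) > 0
  sets <- sets[keep]
  if (!length(sets)) stop("no retained model accepted any ASV")
  asvs <- sort(unique(unlist(sets)))
  pa <- t(vapply(sets, function(s) as.integer(asvs %in% s),
                 integer(length(asvs))))
  colnames(pa) <- asvs
  rownames(pa) <- sprintf("model_%03d", which(keep))
  pa
}

# nearest-rank percentile filter on occurrence counts; ties at the cutoff
# are all included (inclusive >=)
percentile_filter <- function(occ, percentile) {
  if (percentile < 0 || percentile >= 100) stop("percentile must be in [0, 100)")
  if (percentile == 0) return(names(occ))
  k <- max(1L, ceiling(percentile / 100 * length(occ)))
  thr <- sort(occ)[k]
  names(occ)[occ >= thr]
}

#' Co-occurrence network of the most informative ASVs
#'
#' Nodes are the ASVs at or above the given nearest-rank percentile of
#' occurrence counts among the retained models; edge weights count the
#' models containing both ASVs of a pair. Node attributes carry the
#' occurrence count and, when a taxonomy is supplied, the class-level label.
#'
#' @param pa Presence/absence matrix from [presence_absence()] (>= 2 rows).
#' @param percentile Occurrence-count percentile cutoff (default 95; smaller
#'   ensembles warrant smaller cutoffs).
#' @param taxonomy Optional taxonomy table for the class attribute.
#' @return An undirected weighted `igraph` graph.
#' @export
build_cooccurrence <- function(pa, percentile = 95, taxonomy = NULL) {
  if (nrow(pa) < 2) stop("need at least 2 retained models")
  occ <- colSums(pa)
  keep <- percentile_filter(occ, percentile)
  sub <- pa[, keep, drop = FALSE]
  joint <- crossprod(sub)            # pairwise AND counts
  diag(joint) <- 0
  g <- igraph::graph_from_adjacency_matrix(joint, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$occurrence <- occ[igraph::V(g)$name]
  if (!is.null(taxonomy)) {
    igraph::V(g)$class <- taxonomy$Class[match(igraph::V(g)$name, taxonomy$asv_id)]
  }
  g
}

#' Co-exclusion network of the most informative ASVs
#'
#' Same node set as [build_cooccurrence()]; an (unweighted) edge joins two
#' ASVs iff zero retained models contain both — read as informational
#' redundancy between the taxa.
#'
#' @inheritParams build_cooccurrence
#' @return An undirected `igraph` graph.
#' @export
build_coexclusion <- function(pa, percentile = 95, taxonomy = NULL) {
  if (nrow(pa) < 2) stop("need at least 2 retained models")
  occ <- colSums(pa)
  keep <- percentile_filter(occ, percentile)
  if (length(keep) < 2) stop("fewer than 2 ASVs pass the percentile filter")
  sub <- pa[, keep, drop = FALSE]
  joint <- crossprod(sub)
  adj <- (joint == 0) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$occurrence <- occ[igraph::V(g)$name]
  if (!is.null(taxonomy)) {
    igraph::V(g)$class <- taxonomy$Class[match(igraph::V(g)$name, taxonomy$asv_id)]
  }
  g
}

#' Minimal perfect models and their hub structure
#'
#' Returns the retained models whose accepted-ASV set size equals the
#' minimum, and summarizes shared membership: ASVs occurring in more than
#' one minimal set are hubs, listed with their partners.
#'
#' @param models List of retained `screening_model`s (>= 1).
#' @return List with `size`, `sets` (list of character vectors), `models`,
#'   and `hubs` (named list hub ASV -> partner ASVs).
#' @export
minimal_models <- function(models) {
  if (!length(models)) stop("no retained models")
  sets <- lapply(models, function(m) {
    vapply(m$accepted, function(a) a$asv_id, character(1))
  })
  sizes <- lengths(sets)
  k <- min(sizes)
  idx <- which(sizes == k)
  msets <- sets[idx]
  tab <- table(unlist(msets))
  hubs <- lapply(names(tab)[tab > 1], function(h) {
    sort(unique(unlist(lapply(msets, function(s) if (h %in% s) setdiff(s, h)))))
  })
  names(hubs) <- names(tab)[tab > 1]
  list(size = k, sets = msets, models = models[idx], hubs = hubs)
}

#' Taxonomy-based dendrogram of indicator ASVs
#'
#' Pairwise distance between two ASVs is the number of ranks (Kingdom to
#' Genus, six levels) at which their labels differ; average-linkage
#' hierarchical clustering of that matrix gives the tree, serialized as
#' newick. Optional per-ASV occurrence frequencies are attached to the
#' leaves.
#'
#' @param asvs Character vector of ASV ids (>= 2).
#' @param taxonomy Taxonomy table containing every ASV.
#' @param occurrence Optional named occurrence counts; converted to relative
#'   frequencies.
#' @return List with `hclust`, `phylo`, `newick`, `distance`, `frequency`.
#' @export
taxonomy_dendrogram <- function(asvs, taxonomy, occurrence = NULL) {
  stopifnot(length(asvs) >= 2)
  miss <- setdiff(asvs, taxonomy$asv_id)
  if (length(miss)) stop("ASVs missing from taxonomy: ", paste(miss, collapse = ", "))
  lab <- as.matrix(taxonomy[match(asvs, taxonomy$asv_id), TAX_RANKS])
  n <- length(asvs)
  dm <- matrix(0, n, n, dimnames = list(asvs, asvs))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dm[i, j] <- dm[j, i] <- sum(lab[i, ] != lab[j, ])
    }
  }
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  phylo <- ape::as.phylo(hc)
  freq <- NULL
  if (!is.null(occurrence)) {
    freq <- occurrence[asvs] / sum(occurrence[asvs])
  }
  list(hclust = hc, phylo = phylo, newick = ape::write.tree(phylo),
       distance = stats::as.dist(dm), frequency = freq)
}
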