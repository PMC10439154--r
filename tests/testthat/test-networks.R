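fake_model <- function(ids, metric, seed = 1L) {
  structure(list(accepted = lapply(ids, function(a) list(asv_id = a, w = 1L, l = 0L)),
                 metric = metric, base_metric = 0.5, trajectory = numeric(0),
                 hyperparams = list(), task = "classification",
                 seed = as.integer(seed)),
            class = "screening_model")
}

fake_ensemble <- function(models, task = "classification") {
  structure(list(models = models, candidates = character(0), task = task,
                 run_seeds = vapply(models, `[[`, integer(1), "seed"),
                 seed = 1L),
            class = "model_ensemble")
}

test_that("classification retention keeps exactly the perfect models", {
  ens <- fake_ensemble(list(fake_model("a", 1), fake_model("b", 1),
                            fake_model("c", 0.9)))
  expect_length(select_best_models(ens), 2)
  none <- fake_ensemble(list(fake_model("a", 0.8)))
  expect_warning(out <- select_best_models(none), "100%")
  expect_length(out, 0)
})

test_that("regression retention takes the single best model with seed tie-break", {
  ens <- fake_ensemble(list(fake_model("a", 0.5, seed = 5),
                            fake_model("b", 0.7, seed = 9),
                            fake_model("c", 0.7, seed = 2)),
                       task = "regression")
  out <- select_best_models(ens)
  expect_length(out, 1)
  expect_identical(out[[1]]$accepted[[1]]$asv_id, "c")
})

test_that("the presence/absence table has occurrence counts as column sums", {
  models <- list(fake_model(c("a", "b"), 1), fake_model("b", 1),
                 fake_model(character(0), 1), fake_model(c("b", "c"), 1))
  pa <- presence_absence(models)
  expect_identical(nrow(pa), 3L)     # the empty model is dropped
  expect_equal(unname(colSums(pa)[c("a", "b", "c")]), c(1, 3, 1))
  expect_true(all(rowSums(pa) >= 1))
})

test_that("co-occurrence edge weights equal exhaustive pair counting", {
  set.seed(12)
  pa <- matrix(rbinom(60, 1, 0.5), nrow = 6,
               dimnames = list(NULL, letters[1:10]))
  pa[rowSums(pa) == 0, 1] <- 1L
  g <- build_cooccurrence(pa, percentile = 0)
  for (e in seq_len(igraph::ecount(g))) {
    uv <- igraph::ends(g, e)
    expect_equal(igraph::E(g)$weight[e], sum(pa[, uv[1]] & pa[, uv[2]]))
  }
  # an ASV in every model carries the maximal occurrence weight
  pa[, "a"] <- 1L
  g2 <- build_cooccurrence(pa, percentile = 0)
  expect_equal(igraph::V(g2)$occurrence[igraph::V(g2)$name == "a"], 6)
  expect_error(build_cooccurrence(pa, percentile = 100), "percentile")
})

test_that("co-exclusion links exactly the never-together pairs", {
  pa <- cbind(a = c(1, 0, 1), b = c(0, 1, 0), c = c(1, 1, 0))
  g <- build_coexclusion(pa, percentile = 0)
  expect_true(igraph::are_adjacent(g, "a", "b"))
  expect_false(igraph::are_adjacent(g, "a", "c"))   # co-occur in model 1
  expect_false(igraph::are_adjacent(g, "b", "c"))   # co-occur in model 2
  two <- cbind(a = c(1, 0), b = c(0, 1))
  expect_equal(igraph::ecount(build_coexclusion(two, percentile = 0)), 1)
})

test_that("each filtered pair is either co-occurring or co-excluded, never both", {
  set.seed(13)
  pa <- matrix(rbinom(80, 1, 0.4), nrow = 8,
               dimnames = list(NULL, letters[1:10]))
  pa[rowSums(pa) == 0, 2] <- 1L
  co <- build_cooccurrence(pa, percentile = 50)
  cx <- build_coexclusion(pa, percentile = 50)
  nodes <- igraph::V(co)$name
  expect_setequal(nodes, igraph::V(cx)$name)
  for (i in seq_along(nodes)) {
    for (j in seq_len(i - 1)) {
      on_co <- igraph::are_adjacent(co, nodes[i], nodes[j])
      on_cx <- igraph::are_adjacent(cx, nodes[i], nodes[j])
      expect_true(xor(on_co, on_cx))
    }
  }
})

test_that("the percentile filter matches brute-force nearest-rank ranking", {
  occ <- c(a = 5, b = 2, c = 8, d = 2, e = 7, f = 1)
  for (p in c(0, 25, 50, 75, 95)) {
    got <- riverindic:::percentile_filter(occ, p)
    k <- max(1, ceiling(p / 100 * length(occ)))
    thr <- sort(occ)[k]
    expect_setequal(got, names(occ)[occ >= thr])
  }
})

test_that("minimal models group around shared hub members", {
  models <- list(fake_model(c("hub", "p1"), 1), fake_model(c("hub", "p2"), 1),
                 fake_model(c("x", "y", "z"), 1))
  mm <- minimal_models(models)
  expect_identical(mm$size, 2L)
  expect_length(mm$sets, 2)
  expect_identical(names(mm$hubs), "hub")
  expect_setequal(mm$hubs$hub, c("p1", "p2"))
  single <- minimal_models(list(fake_model("solo", 1)))
  expect_identical(single$sets[[1]], "solo")
})

test_that("taxonomic distances count differing ranks", {
  tax <- toy_taxonomy()
  dn <- taxonomy_dendrogram(c("a1", "a2", "a3", "a4"), tax)
  dm <- as.matrix(dn$distance)
  expect_equal(dm["a1", "a2"], 1)   # same family, different genus
  expect_equal(dm["a1", "a3"], 2)   # family + genus differ
  expect_equal(dm["a1", "a4"], 6)   # all ranks differ
  tax2 <- rbind(tax, transform(tax[1, ], asv_id = "a1bis"))
  dn2 <- taxonomy_dendrogram(c("a1", "a1bis"), tax2)
  expect_equal(as.numeric(dn2$distance), 0)
})

test_that("the newick serialization round-trips through ape", {
  tax <- toy_taxonomy()
  occ <- c(a1 = 4, a2 = 2, a3 = 3, a4 = 1)
  dn <- taxonomy_dendrogram(tax$asv_id, tax, occurrence = occ)
  back <- ape::read.tree(text = dn$newick)
  expect_setequal(back$tip.label, tax$asv_id)
  expect_equal(as.numeric(suppressWarnings(ape::dist.topo(back, dn$phylo))), 0)
  expect_equal(sum(dn$frequency), 1)
})

test_that("missing taxa are reported by name", {
  expect_error(taxonomy_dendrogram(c("a1", "ghost"), toy_taxonomy()), "ghost")
})
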