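#' Prevalence and coefficient of variation per taxon
#'
#' Prevalence is the fraction of samples in which a taxon is detected
#' (abundance > 0). The coefficient of variation is the sample (n-1) standard
#' deviation of the taxon's relative abundances divided by their mean;
#' computing it on relative abundances keeps library size out of the
#' variance. Taxa with zero mean abundance get an undefined (NA) cv with
#' `cv_defined = FALSE`.
#'
#' @param matrix Samples x taxa abundance matrix (counts or relative), >= 2
#'   samples.
#' @return Data.frame with columns `taxon`, `prevalence`, `cv`, `cv_defined`.
#' @export
prevalence_cv <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2) stop("at least 2 samples are required (cv undefined otherwise)")
  rs <- rowSums(matrix)
  rel <- sweep(matrix, 1, ifelse(rs == 0, 1, rs), "/")
  m <- colMeans(rel)
  s <- apply(rel, 2, stats::sd)
  cv <- ifelse(m == 0, NA_real_, s / m)
  data.frame(
    taxon = colnames(matrix),
    prevalence = colMeans(matrix > 0),
    cv = cv,
    cv_defined = m > 0,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Rank bioindicator candidates on the prevalence-CV plane
#'
#' Taxa that are both broadly present and highly variable are the candidate
#' bioindicators. The reproducible selection rule is: order taxa by
#' non-dominated (Pareto) front layer on (prevalence, cv), within a layer by
#' the product of min-max standardized prevalence and cv (descending), ties
#' broken lexicographically by taxon id; the top `n_top` are flagged.
#'
#' @param screens Output of [prevalence_cv()].
#' @param n_top Number of taxa to flag (6 at phylum and 15 at genus level are
#'   the conventional choices).
#' @return `screens` with added `score`, `front`, `rank`, `candidate`
#'   columns, ordered by rank.
#' @export
select_candidates <- function(screens, n_top) {
  stopifnot(n_top >= 1)
  ok <- screens[screens$cv_defined & !is.na(screens$cv), , drop = FALSE]
  if (!nrow(ok)) stop("all taxa have undefined cv; nothing to rank")
  mm <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(1, length(x)) else (x - r[1]) / diff(r)
  }
  ok$score <- mm(ok$prevalence) * mm(ok$cv)
  ok$front <- pareto_fronts(ok$prevalence, ok$cv)
  ord <- order(ok$front, -ok$score, ok$taxon)
  ok <- ok[ord, , drop = FALSE]
  ok$rank <- seq_len(nrow(ok))
  ok$candidate <- ok$rank <= n_top
  rownames(ok) <- NULL
  ok
}

# non-dominated sorting layers (maximize both coordinates)
pareto_fronts <- function(x, y) {
  n <- length(x)
  front <- integer(n)
  remaining <- seq_len(n)
  layer <- 0L
  while (length(remaining)) {
    layer <- layer + 1L
    dominated <- vapply(remaining, function(i) {
      any((x[remaining] >= x[i] & y[remaining] > y[i]) |
            (x[remaining] > x[i] & y[remaining] >= y[i]))
    }, logical(1))
    front[remaining[!dominated]] <- layer
    remaining <- remaining[dominated]
  }
  front
}
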