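#' @keywords internal
"_PACKAGE"

TAX_RANKS <- c("Kingdom", "Phylum", "Class", "Order", "Family", "Genus")

#' Construct a validated river dataset
#'
#' Bundles the abundance matrix, taxonomy table and sample metadata, checks
#' the cross-table identifier contracts, and orders samples upstream to
#' downstream (decreasing distance to mouth) within each transect.
#'
#' @param abundance Numeric samples x taxa matrix with sample ids as rownames.
#' @param taxonomy Data.frame with columns `asv_id` and the six ranks
#'   Kingdom..Genus.
#' @param metadata Data.frame with at least `sample_id`, `transect`,
#'   `distance_to_mouth_km`.
#' @return An object of class `river_dataset`.
#' @export
new_river_dataset <- function(abundance, taxonomy, metadata) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance))) stop("abundance must have sample ids as rownames")
  if (any(abundance < 0)) stop("abundance contains negative counts")
  need <- c("sample_id", "transect", "distance_to_mouth_km")
  miss_col <- setdiff(need, names(metadata))
  if (length(miss_col)) stop("metadata lacks columns: ", paste(miss_col, collapse = ", "))
  only_ab <- setdiff(rownames(abundance), metadata$sample_id)
  only_meta <- setdiff(metadata$sample_id, rownames(abundance))
  if (length(only_ab) || length(only_meta)) {
    stop("sample id mismatch between abundance and metadata; ",
         "only in abundance: [", paste(only_ab, collapse = ", "), "]; ",
         "only in metadata: [", paste(only_meta, collapse = ", "), "]")
  }
  if (!"asv_id" %in% names(taxonomy)) stop("taxonomy lacks an asv_id column")
  missing_tax <- setdiff(colnames(abundance), taxonomy$asv_id)
  if (length(missing_tax)) {
    stop("taxa absent from taxonomy: ", paste(missing_tax, collapse = ", "))
  }
  ord <- order(metadata$transect, -metadata$distance_to_mouth_km)
  metadata <- metadata[ord, , drop = FALSE]
  rownames(metadata) <- NULL
  abundance <- abundance[metadata$sample_id, , drop = FALSE]
  if ("status_class" %in% names(metadata) && !is.factor(metadata$status_class)) {
    metadata$status_class <- factor(metadata$status_class,
                                    levels = sort(unique(metadata$status_class)),
                                    ordered = TRUE)
  }
  structure(list(abundance = abundance, taxonomy = taxonomy, metadata = metadata),
            class = "river_dataset")
}

#' @export
print.river_dataset <- function(x, ...) {
  cat("river_dataset:", nrow(x$abundance), "samples x", ncol(x$abundance), "taxa;",
      length(unique(x$metadata$transect)), "transects\n")
  invisible(x)
}

#' Load a dataset from ASV, taxonomy and metadata tables
#'
#' Reads tab-delimited tables (UTF-8, header row required; the abundance
#' table may alternatively be a BIOM file, read through the `biomformat`
#' package), validates the identifier contracts, and returns samples ordered
#' upstream to downstream within each transect. The first column of the ASV
#' table holds sample ids; remaining columns are taxa. `status_class`, when
#' present, is parsed as an ordered factor. Log-scale microbiological
#' variables are expected pre-transformed; no re-transformation is applied.
#'
#' @param asv_path Path to the ASV table (TSV or .biom).
#' @param taxonomy_path Path to the taxonomy TSV.
#' @param metadata_path Path to the metadata TSV.
#' @return A `river_dataset`.
#' @export
load_dataset <- function(asv_path, taxonomy_path, metadata_path) {
  for (p in c(asv_path, taxonomy_path, metadata_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  if (grepl("\\.biom$", asv_path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the biomformat package")
    }
    b <- biomformat::read_biom(asv_path)
    ab <- t(as.matrix(biomformat::biom_data(b)))  # biom stores taxa x samples
  } else {
    tab <- utils::read.delim(asv_path, check.names = FALSE, stringsAsFactors = FALSE)
    ab <- as.matrix(tab[, -1, drop = FALSE])
    rownames(ab) <- as.character(tab[[1]])
  }
  if (!is.numeric(ab)) stop("abundance table contains non-numeric entries")
  tax <- utils::read.delim(taxonomy_path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.delim(metadata_path, check.names = FALSE, stringsAsFactors = FALSE)
  new_river_dataset(ab, tax, meta)
}

#' Hellinger transformation
#'
#' Square root of per-sample relative abundances: cell (i,j) becomes
#' `sqrt(x_ij / rowsum_i)`. All-zero rows map to all-zero rows. Nonzero rows
#' of the result have unit sum of squares, which makes Euclidean-geometry
#' ordination appropriate for species data.
#'
#' @param counts Nonnegative samples x taxa matrix.
#' @return Matrix of the same shape.
#' @export
hellinger_transform <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative entries are not allowed")
  rs <- rowSums(counts)
  out <- sqrt(sweep(counts, 1, ifelse(rs == 0, 1, rs), "/"))
  dimnames(out) <- dimnames(counts)
  out
}

#' Aggregate an abundance matrix to a taxonomic rank
#'
#' Sums columns sharing the same label at the given rank; per-sample totals
#' are conserved. Taxa unlabeled at that rank (NA or empty) are pooled into a
#' single `unclassified_<rank>` column.
#'
#' @param matrix Samples x taxa matrix, taxa as colnames.
#' @param taxonomy Data.frame with `asv_id` and rank columns.
#' @param rank One of "Phylum", "Class", "Family", "Genus".
#' @return Samples x groups matrix.
#' @export
aggregate_taxa <- function(matrix, taxonomy, rank) {
  rank <- as.character(rank)
  if (!rank %in% c("Phylum", "Class", "Family", "Genus")) {
    stop("rank must be one of Phylum, Class, Family, Genus (got '", rank, "')")
  }
  matrix <- as.matrix(matrix)
  lab <- taxonomy[[rank]][match(colnames(matrix), taxonomy$asv_id)]
  if (anyNA(match(colnames(matrix), taxonomy$asv_id))) {
    stop("taxa absent from taxonomy: ",
         paste(setdiff(colnames(matrix), taxonomy$asv_id), collapse = ", "))
  }
  lab[is.na(lab) | lab == ""] <- paste0("unclassified_", rank)
  agg <- t(rowsum(t(matrix), group = lab))
  agg[, order(colnames(agg)), drop = FALSE]
}

#' Predictive mean matching imputation
#'
#' For each numeric variable with missing entries, a linear model of the
#' variable on the complete numeric covariates is fit on the observed cases;
#' every case gets a predicted mean, and each missing entry is replaced by the
#' observed value of one of the `k_donors` donors whose predicted means lie
#' closest to the missing case's predicted mean (the donor is drawn uniformly
#' among the k, so every imputed value is an actually observed value).
#'
#' @param metadata Data.frame; non-numeric columns pass through untouched.
#' @param k_donors Number of candidate donors (default 5, the common
#'   convention).
#' @param seed Integer seed for the donor draw.
#' @return Data.frame with missing numeric entries imputed.
#' @export
impute_pmm <- function(metadata, k_donors = 5, seed = 1) {
  stopifnot(k_donors >= 1)
  num_cols <- names(metadata)[vapply(metadata, is.numeric, logical(1))]
  target <- num_cols[vapply(metadata[num_cols], anyNA, logical(1))]
  if (!length(target)) return(metadata)
  complete_cov <- setdiff(num_cols[!vapply(metadata[num_cols], anyNA, logical(1))],
                          target)
  set.seed(as.integer(seed))
  out <- metadata
  for (v in target) {
    y <- metadata[[v]]
    obs <- which(!is.na(y))
    mis <- which(is.na(y))
    if (!length(obs)) stop("variable '", v, "' is entirely missing")
    if (length(complete_cov)) {
      X <- metadata[complete_cov]
      fit <- stats::lm(stats::reformulate(complete_cov, response = v),
                       data = cbind(metadata[v], X))
      pred <- stats::predict(fit, newdata = X)
    } else {
      pred <- rep(mean(y[obs]), nrow(metadata))  # no covariates: random donor
    }
    for (i in mis) {
      d <- abs(pred[obs] - pred[i])
      k <- min(k_donors, length(obs))
      donors <- obs[order(d, obs)[seq_len(k)]]  # deterministic tie-break by row
      out[[v]][i] <- y[donors[sample.int(k, 1)]]
    }
  }
  out
}
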