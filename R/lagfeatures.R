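#' Order samples by distance from the source
#'
#' Returns the row order placing samples upstream first (decreasing distance
#' to mouth), with transect as a deterministic tie-break for stations shared
#' across transects. This is the observation order used for the ordered
#' train/test split of the screening models.
#'
#' @param metadata Sample metadata with `distance_to_mouth_km` and `transect`.
#' @return Integer permutation of the rows.
#' @export
order_by_flow <- function(metadata) {
  order(-metadata$distance_to_mouth_km, metadata$transect)
}

#' Base design matrix for the screening models
#'
#' The design matrix initially contains the sample index (0-based, in
#' flow order), an integer transect code, and the distance to the river
#' mouth — the covariates that encode longitudinal continuity and travel
#' time. Engineered ASV columns are appended by [lagged_design_matrix()].
#'
#' @param metadata Sample metadata ordered by [order_by_flow()].
#' @return Data.frame with columns `sample_idx`, `transect_code`,
#'   `distance_to_mouth_km`, plus hidden `transect` ordering metadata in
#'   attributes.
#' @export
base_design <- function(metadata) {
  out <- data.frame(
    sample_idx = seq_len(nrow(metadata)) - 1L,
    transect_code = as.integer(factor(metadata$transect)),
    distance_to_mouth_km = metadata$distance_to_mouth_km
  )
  attr(out, "transect") <- as.character(metadata$transect)
  attr(out, "sample_id") <- metadata$sample_id
  out
}

#' Append windowed-standardized lagged ASV columns to a design matrix
#'
#' For each spec (ASV, window w, lag l) and within each transect (samples
#' ordered upstream to downstream), the engineered value at site i is the
#' abundance at site i - l, centered and scaled by the mean and sample sd of
#' the w sites ending at i - l. `w = 1` means the raw lagged value (no
#' scaling). Sites without enough upstream history use a clamped source
#' index and a truncated window over the sites actually available (warm-up),
#' so transects keep equal length and no engineered value ever depends on a
#' downstream site.
#'
#' @param base Output of [base_design()] (carries the transect attribute).
#' @param series Samples x taxa matrix aligned with the rows of `base`
#'   (typically Hellinger-transformed abundances).
#' @param specs List of specs, each a list/vector with `asv_id`, `w`, `l`.
#' @return `base` with one numeric column per spec appended, named
#'   `<asv>_w<w>_l<l>`.
#' @export
lagged_design_matrix <- function(base, series, specs) {
  tr <- attr(base, "transect")
  if (is.null(tr)) stop("base must come from base_design() (transect attribute missing)")
  series <- as.matrix(series)
  stopifnot(nrow(series) == nrow(base))
  out <- base
  for (sp in specs) {
    asv <- sp$asv_id
    w <- as.integer(sp$w)
    l <- as.integer(sp$l)
    if (!asv %in% colnames(series)) stop("unknown ASV: ", asv)
    if (w < 1) stop("window must be >= 1")
    if (l < 0) stop("lag must be >= 0")
    col <- numeric(nrow(base))
    for (t in unique(tr)) {
      idx <- which(tr == t)
      if (l >= length(idx)) {
        stop("lag ", l, " is not smaller than the length of transect '", t, "'")
      }
      col[idx] <- lag_window_series(series[idx, asv], w = w, l = l)
    }
    out[[sprintf("%s_w%d_l%d", asv, w, l)]] <- col
  }
  attr(out, "transect") <- tr
  attr(out, "sample_id") <- attr(base, "sample_id")
  out
}

design_features <- function(design) {
  as.matrix(design[, setdiff(names(design), character(0)), drop = FALSE])
}
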