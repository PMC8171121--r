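# Detection-flag filtering and quantile normalization.
#
# The workflow mirrors vendor practice for one-color lncRNA arrays: features
# detected (Present or Marginal) in at least `min_detected` of the samples are
# retained, then all sample columns are forced onto a common distribution by
# averaging order statistics. Filtering runs before normalization so the
# order-statistic pool contains only reliably measured features.

#' Filter features by detection flags
#'
#' Retains exactly those features flagged Present or Marginal in at least
#' `min_detected` samples ("All Targets Value" filter). The sample set is
#' unchanged and feature order is preserved.
#'
#' @param bundle An [expression_bundle()].
#' @param min_detected Minimum number of P/M samples required (default 4,
#'   i.e. half of the canonical 8-sample design).
#' @return The filtered bundle, with attribute `"preprocess_report"` holding
#'   `n_features_in` and `n_features_pass_flags`.
#' @export
filter_by_flags <- function(bundle, min_detected = 4L) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (min_detected < 0) stop("`min_detected` must be non-negative")
  if (min_detected > ncol(bundle$values))
    stop("`min_detected` exceeds the number of samples")
  detected <- rowSums(bundle$flags == "P" | bundle$flags == "M")
  keep <- detected >= min_detected
  out <- expression_bundle(bundle$values[keep, , drop = FALSE],
                           bundle$flags[keep, , drop = FALSE],
                           scale = bundle$scale)
  attr(out, "preprocess_report") <- list(
    n_features_in = nrow(bundle$values),
    n_features_pass_flags = sum(keep),
    min_detected = min_detected)
  out
}

#' Quantile-normalize an expression bundle
#'
#' Forces every sample column to the identical multiset of values, namely the
#' across-sample mean of order statistics; within each column the rank order
#' of values is preserved. Ties within a column all receive the mean of the
#' corresponding order-statistic means (average-rank tie policy), which makes
#' the transform idempotent.
#'
#' @param bundle Linear-scale [expression_bundle()] with at least one feature
#'   and one sample.
#' @return Normalized bundle (same flags, same scale marker).
#' @export
quantile_normalize <- function(bundle) {
  stopifnot(inherits(bundle, "expression_bundle"))
  x <- bundle$values
  if (nrow(x) < 1L || ncol(x) < 1L) stop("need at least one feature and sample")
  norm <- quantile_normalize_matrix(x)
  expression_bundle(norm, bundle$flags, scale = bundle$scale)
}

# Plain-matrix workhorse: reference distribution = rowMeans of the sorted
# columns; each column maps rank -> reference value, averaging over ties.
quantile_normalize_matrix <- function(x) {
  ref <- rowMeans(apply(x, 2L, sort.int, method = "quick"))
  out <- x
  for (j in seq_len(ncol(x))) {
    rk <- rank(x[, j], ties.method = "average")
    # non-integer (tied) ranks interpolate between adjacent reference values
    lo <- floor(rk); hi <- ceiling(rk)
    out[, j] <- (ref[lo] + ref[hi]) / 2
  }
  out
}

#' Log2-transform a linear-scale bundle
#'
#' @param bundle Linear-scale [expression_bundle()].
#' @param offset Non-negative constant added before taking logs. The default
#'   0 assumes the flag filter already removed zero-intensity features.
#' @return Bundle with `value <- log2(value + offset)` and scale `"log2"`.
#' @export
log2_transform <- function(bundle, offset = 0) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (bundle$scale != "linear") stop("bundle is already on the log2 scale")
  if (offset < 0) stop("`offset` must be non-negative")
  if (any(bundle$values + offset <= 0))
    stop("log2 undefined: some value + offset <= 0")
  expression_bundle(log2(bundle$values + offset), bundle$flags, scale = "log2")
}

#' Run the standard preprocessing chain
#'
#' Flag filter, then quantile normalization (filter-first so the
#' order-statistic pool excludes undetected features).
#'
#' @inheritParams filter_by_flags
#' @return List with `bundle` (normalized, linear scale) and `report`.
#' @export
preprocess <- function(bundle, min_detected = 4L) {
  filtered <- filter_by_flags(bundle, min_detected)
  rep <- attr(filtered, "preprocess_report")
  norm <- quantile_normalize(filtered)
  rep$normalization_applied <- TRUE
  list(bundle = norm, report = rep)
}
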