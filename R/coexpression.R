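# Coding--non-coding (CNC) co-expression network: lncRNA-mRNA edges defined
# by thresholded Pearson correlation across all samples pooled. At the
# canonical 8-sample design the p gate is mathematically redundant: |r| >=
# 0.9 with n = 8 already gives p ~ 0.0023 < 0.005.

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors, n >= 3, both non-constant.
#' @return r, clamped to [-1, 1] against floating-point rounding.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  max(-1, min(1, r))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact null transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on
#' `n - 2` degrees of freedom; `|r| = 1` gives p = 0.
#'
#' @param r Correlation in [-1, 1].
#' @param n Sample size, >= 3.
#' @export
correlation_p <- function(r, n) {
  if (n < 3) stop("need n >= 3")
  if (abs(r) > 1) stop("|r| must be <= 1")
  if (abs(r) == 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), n - 2)
}

#' Build the coding--non-coding co-expression network
#'
#' One edge per (lncRNA, mRNA) pair with `|r| >= r_min` and `p <= p_max`,
#' computed on the bundle's signal across all samples pooled (log2 scale
#' recommended).
#'
#' @param bundle Normalized [expression_bundle()].
#' @param lnc_ids,mrna_ids Disjoint feature id vectors, all present in the
#'   bundle.
#' @param r_min Absolute-correlation gate (default 0.9, inclusive).
#' @param p_max Correlation p gate (default 0.005, inclusive).
#' @return List with `edges` (data frame `lncRNA`, `mRNA`, `r`, `p`, `sign`)
#'   and `summary` (`n_nodes`, `n_edges`, `n_positive`, `n_negative`);
#'   nodes are counted only when they carry at least one edge.
#' @export
build_cnc <- function(bundle, lnc_ids, mrna_ids, r_min = 0.9, p_max = 0.005) {
  stopifnot(inherits(bundle, "expression_bundle"))
  both <- intersect(lnc_ids, mrna_ids)
  if (length(both))
    stop("ids present in both lists: ", paste(both, collapse = ", "))
  miss <- setdiff(c(lnc_ids, mrna_ids), rownames(bundle$values))
  if (length(miss)) stop("ids absent from bundle: ", paste(miss, collapse = ", "))
  n <- ncol(bundle$values)
  if (n < 3L) stop("need >= 3 samples for correlation")
  lx <- t(bundle$values[lnc_ids, , drop = FALSE])
  mx <- t(bundle$values[mrna_ids, , drop = FALSE])
  rmat <- stats::cor(lx, mx)
  rmat[rmat > 1] <- 1; rmat[rmat < -1] <- -1
  hits <- which(abs(rmat) >= r_min, arr.ind = TRUE)
  edges <- data.frame(lncRNA = character(0), mRNA = character(0),
                      r = numeric(0), p = numeric(0), sign = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(hits)) {
    r <- rmat[hits]
    p <- vapply(r, correlation_p, 0, n = n)
    keep <- p <= p_max
    edges <- data.frame(
      lncRNA = lnc_ids[hits[, 1L]][keep],
      mRNA = mrna_ids[hits[, 2L]][keep],
      r = r[keep], p = p[keep],
      sign = ifelse(r[keep] > 0, "positive", "negative"),
      stringsAsFactors = FALSE)
    edges <- edges[order(edges$lncRNA, edges$mRNA), , drop = FALSE]
    rownames(edges) <- NULL
  }
  summary <- list(
    n_nodes = length(unique(c(edges$lncRNA, edges$mRNA))),
    n_edges = nrow(edges),
    n_positive = sum(edges$sign == "positive"),
    n_negative = sum(edges$sign == "negative"))
  list(edges = edges, summary = summary)
}
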