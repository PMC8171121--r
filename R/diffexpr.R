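# Two-group differential expression and microarray/qPCR concordance.
#
# Conventions (all configurable): t statistics and p-values are computed on
# log2-normalized signal (log intensities in each group are approximately
# normal); fold changes are reported as linear ratios >= 1 with an explicit
# up/down direction relative to the case group; the pooled-variance Student
# t is the default because it reproduces the demographic-table p-values of
# the reference cohort exactly (Welch is available by flag). Raw p-values
# are used for the DE call (no multiplicity correction), with a BH-adjusted
# column emitted alongside for users who want it.

#' Two-sample t-test
#'
#' @param xs,ys Numeric vectors, each of length >= 2, finite.
#' @param equal_variance If `TRUE` (default) the pooled-variance Student
#'   test; otherwise Welch.
#' @return List with `t`, `p` (two-sided), `df`, and `degenerate` (`TRUE`
#'   when both groups have zero variance: equal means give p = 1 by
#'   convention, unequal means the p -> 0 limit).
#' @export
t_test_two_sample <- function(xs, ys, equal_variance = TRUE) {
  if (length(xs) < 2L || length(ys) < 2L) stop("each group needs >= 2 values")
  if (!all(is.finite(xs)) || !all(is.finite(ys))) stop("values must be finite")
  nx <- length(xs); ny <- length(ys)
  mx <- mean(xs); my <- mean(ys)
  vx <- stats::var(xs); vy <- stats::var(ys)
  if (equal_variance) {
    df <- nx + ny - 2
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- if (se > 0) (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)) else NA_real_
  }
  if (!is.finite(se) || se == 0) {
    if (isTRUE(all.equal(mx, my))) {
      return(list(t = 0, p = 1, df = df, degenerate = TRUE))
    }
    return(list(t = sign(mx - my) * Inf, p = 0, df = df, degenerate = TRUE))
  }
  t <- (mx - my) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df, degenerate = FALSE)
}

#' Linear fold change with direction
#'
#' @param mean_case,mean_control Positive linear-scale group means.
#' @return List with `fold_change` (`max(ratio, 1/ratio) >= 1`) and
#'   `direction` (`"up"` iff case > control; an exact tie is labelled
#'   `"down"` and never passes any fold-change gate anyway).
#' @export
fold_change_linear <- function(mean_case, mean_control) {
  if (any(c(mean_case, mean_control) <= 0))
    stop("fold change needs positive group means")
  ratio <- mean_case / mean_control
  list(fold_change = max(ratio, 1 / ratio),
       direction = if (ratio > 1) "up" else "down")
}

#' Call differential expression between two groups
#'
#' One record per feature. The DE subset is
#' `fold_change >= fc_min & p_value < p_max` (fold-change gate inclusive,
#' p gate exclusive, as printed cutoffs are conventionally read). Tests run
#' on log2 signal; fold changes and the `raw_intensity` column (the larger
#' of the two linear group means) on the linear scale.
#'
#' @param bundle Normalized [expression_bundle()] (linear or log2 scale).
#' @param design A [group_design()] covering the bundle's samples.
#' @param annotation Optional [feature_annotation()] supplying `biotype`
#'   and `gene_symbol` columns.
#' @param fc_min Fold-change cutoff (default 1.5, inclusive).
#' @param p_max P-value cutoff (default 0.05, exclusive).
#' @param equal_variance Pooled t (default) or Welch.
#' @param log_offset Offset used if the bundle has to be log-transformed.
#' @return Data frame with columns `feature_id`, `biotype`, `gene_symbol`,
#'   `mean_case`, `mean_control`, `fold_change`, `direction`, `t_statistic`,
#'   `p_value`, `p_adj` (BH), `raw_intensity`, `de` (logical),
#'   `boundary` (fold change exactly at `fc_min` or p exactly at `p_max`).
#' @export
call_de <- function(bundle, design, annotation = NULL,
                    fc_min = 1.5, p_max = 0.05,
                    equal_variance = TRUE, log_offset = 0) {
  stopifnot(inherits(bundle, "expression_bundle"))
  miss <- setdiff(design$sample_id, colnames(bundle$values))
  if (length(miss)) stop("design samples absent from bundle: ",
                         paste(miss, collapse = ", "))
  case_ids <- design$sample_id[design$group == "case"]
  ctrl_ids <- design$sample_id[design$group == "control"]
  if (length(case_ids) < 2L || length(ctrl_ids) < 2L)
    stop("each group needs >= 2 samples")
  if (bundle$scale == "linear") {
    lin <- bundle$values
    logm <- log2(lin + log_offset)
    if (any(!is.finite(logm)))
      stop("log2 undefined for some intensities; supply a positive log_offset")
  } else {
    logm <- bundle$values
    lin <- 2^logm
  }
  lx <- logm[, case_ids, drop = FALSE]
  ly <- logm[, ctrl_ids, drop = FALSE]
  nx <- ncol(lx); ny <- ncol(ly)
  mx <- rowMeans(lx); my <- rowMeans(ly)
  vx <- apply(lx, 1L, stats::var); vy <- apply(ly, 1L, stats::var)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
  if (equal_variance) {
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    dfv <- rep(df, length(se))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    dfv <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mx - my) / se
  p <- 2 * stats::pt(-abs(t), dfv)
  zero <- !is.finite(se) | se == 0
  if (any(zero)) {
    eq <- zero & abs(mx - my) < 1e-12
    t[zero] <- ifelse(eq[zero], 0, sign(mx - my)[zero] * Inf)
    p[zero] <- ifelse(eq[zero], 1, 0)
  }
  mean_case <- rowMeans(lin[, case_ids, drop = FALSE])
  mean_control <- rowMeans(lin[, ctrl_ids, drop = FALSE])
  ratio <- mean_case / mean_control
  fc <- pmax(ratio, 1 / ratio)
  direction <- ifelse(ratio > 1, "up", "down")
  ids <- rownames(bundle$values)
  biotype <- rep(NA_character_, length(ids))
  symbol <- ids
  if (!is.null(annotation)) {
    m <- match(ids, annotation$feature_id)
    biotype <- annotation$biotype[m]
    symbol <- ifelse(is.na(m), ids, annotation$gene_symbol[m])
  }
  out <- data.frame(
    feature_id = ids, biotype = biotype, gene_symbol = symbol,
    mean_case = mean_case, mean_control = mean_control,
    fold_change = fc, direction = direction,
    t_statistic = t, p_value = p,
    p_adj = stats::p.adjust(p, method = "BH"),
    raw_intensity = pmax(mean_case, mean_control),
    stringsAsFactors = FALSE, row.names = NULL)
  out$de <- out$fold_change >= fc_min & out$p_value < p_max
  out$boundary <- out$fold_change == fc_min | out$p_value == p_max
  attr(out, "de_counts") <- de_counts(out)
  out
}

# up/down counts per biotype for the log line and reports
de_counts <- function(de_table) {
  sub <- de_table[de_table$de, , drop = FALSE]
  bt <- ifelse(is.na(sub$biotype), "unknown", sub$biotype)
  as.data.frame(table(biotype = bt, direction = sub$direction),
                stringsAsFactors = FALSE)
}

#' Select top candidates for qPCR validation
#'
#' Applies the strict validation gates (fold change > `fc_min`,
#' p < `p_max`, raw intensity > `intensity_min`) then keeps the top
#' `n_each` features per direction (and per biotype when available) ranked
#' by fold change descending, p ascending, feature id ascending.
#'
#' @param records DE table from [call_de()].
#' @param fc_min Strict fold-change gate (default 2).
#' @param p_max Strict p gate (default 0.05).
#' @param intensity_min Strict raw-intensity gate (default 500).
#' @param n_each Candidates per direction (default 10).
#' @return Subset of `records` with a `rank_in_group` column; a warning is
#'   raised when a group has fewer than `n_each` survivors.
#' @export
select_validation_candidates <- function(records, fc_min = 2, p_max = 0.05,
                                         intensity_min = 500, n_each = 10L) {
  q <- records[records$fold_change > fc_min &
               records$p_value < p_max &
               records$raw_intensity > intensity_min, , drop = FALSE]
  grp <- if (all(is.na(q$biotype))) q$direction
         else paste(q$biotype, q$direction, sep = ".")
  pieces <- lapply(split(q, grp), function(d) {
    d <- d[order(-d$fold_change, d$p_value, d$feature_id), , drop = FALSE]
    if (nrow(d) < n_each)
      warning(sprintf("only %d candidates available for %s %s (requested %d)",
                      nrow(d), d$biotype[1L], d$direction[1L], n_each))
    d <- utils::head(d, n_each)
    d$rank_in_group <- seq_len(nrow(d))
    d
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Microarray/qPCR concordance rate
#'
#' @param candidates Candidate table (needs `feature_id`, `direction`).
#' @param qpcr Data frame with `feature_id` and `qpcr_call` in
#'   `c("up", "down", "unchanged")`, one row per candidate.
#' @return Percentage (0-100) of candidates whose qPCR call equals their
#'   microarray direction.
#' @export
concordance_rate <- function(candidates, qpcr) {
  m <- match(candidates$feature_id, qpcr$feature_id)
  if (anyNA(m))
    stop("missing qPCR outcome for: ",
         paste(candidates$feature_id[is.na(m)], collapse = ", "))
  calls <- qpcr$qpcr_call[m]
  if (!all(calls %in% c("up", "down", "unchanged")))
    stop("qpcr_call must be one of up/down/unchanged")
  100 * sum(calls == candidates$direction) / nrow(candidates)
}

#' Hierarchical-clustering leaf order
#'
#' Agglomerative clustering of features under 1 - Pearson correlation
#' distance with average (UPGMA) linkage; returns the dendrogram leaf order.
#' A constant (zero-variance) feature has undefined correlation and is
#' assigned the maximal distance 2 to every other feature, with a warning.
#'
#' @param bundle An [expression_bundle()].
#' @param features Feature ids to cluster (>= 2).
#' @return Character vector: `features` in leaf order.
#' @export
cluster_order <- function(bundle, features) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (length(features) < 2L) stop("need >= 2 features to cluster")
  x <- bundle$values[features, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  const <- sds == 0
  if (any(const))
    warning("constant features assigned maximal distance: ",
            paste(features[const], collapse = ", "))
  cc <- suppressWarnings(stats::cor(t(x)))
  d <- 1 - cc
  d[is.na(d)] <- 2
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  features[hc$order]
}
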