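# Fisher-exact over-representation of a study gene list against
# user-supplied gene sets (GO/KEGG-style GMT input), scored as -log10(p).
# The background defaults, at the pipeline level, to all features surviving
# the detection-flag filter -- the array-design universe -- not the genome.

#' Fisher-exact gene-set over-representation
#'
#' For each set the one-sided (over-representation) Fisher exact p-value is
#' computed on the 2x2 table (k, n-k; K-k, N-n-K+k) where k = study genes in
#' the set, K = population genes in the set, n = study size, N = population
#' size. Sets are intersected with the population first.
#'
#' @param study Character vector of study gene symbols (must be a subset of
#'   `population`).
#' @param population Background gene symbols.
#' @param sets Gene-set list from [read_gmt()].
#' @param p_max Significance cutoff on the raw p-value (default 0.05,
#'   exclusive). No multiplicity correction is applied to the call; a BH
#'   column is emitted for reference.
#' @param two_sided Use the two-sided Fisher test instead (default `FALSE`).
#' @return Data frame sorted by p ascending: `set_id`, `name`, `category`,
#'   `k`, `K`, `n`, `N`, `p_value`, `p_adj`, `score` (-log10 p),
#'   `significant`. A study of size 0 yields an empty result.
#' @export
fisher_enrich <- function(study, population, sets, p_max = 0.05,
                          two_sided = FALSE) {
  study <- unique(study); population <- unique(population)
  off <- setdiff(study, population)
  if (length(off))
    stop("study genes absent from population: ", paste(off, collapse = ", "))
  empty <- data.frame(set_id = character(0), name = character(0),
                      category = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      p_adj = numeric(0), score = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (!length(study) || !length(sets)) return(empty)
  N <- length(population); n <- length(study)
  rows <- lapply(sets, function(s) {
    members <- intersect(s$members, population)
    K <- length(members)
    k <- length(intersect(members, study))
    p <- if (two_sided) {
      stats::fisher.test(matrix(c(k, n - k, K - k, N - n - K + k), 2L))$p.value
    } else {
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    }
    data.frame(set_id = s$set_id, name = s$name, category = s$category,
               k = k, K = K, n = n, N = N, p_value = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$score <- vapply(out$p_value, score_transform, 0)
  out$significant <- out$p_value < p_max
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment score transform
#'
#' `score = -log10(p)`; p = 0 (possible only through underflow) is capped
#' at `cap` and flagged with attribute `"capped"`.
#'
#' @param p P-value in [0, 1].
#' @param cap Maximum score assigned to p = 0 (default 300, roughly the
#'   double-precision underflow boundary).
#' @export
score_transform <- function(p, cap = 300) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (p == 0) return(structure(cap, capped = TRUE))
  -log10(p)
}

#' Top-scoring sets per category
#'
#' @param records Data frame from [fisher_enrich()].
#' @param n Sets to keep per category (default 10).
#' @param significant_only Restrict to records passing the p gate.
#' @export
top_by_category <- function(records, n = 10L, significant_only = TRUE) {
  if (significant_only) records <- records[records$significant, , drop = FALSE]
  pieces <- lapply(split(records, records$category), function(d)
    utils::head(d[order(d$p_value, d$set_id), , drop = FALSE], n))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
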