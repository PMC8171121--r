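# Cis nearby-gene pairing: DE lncRNAs matched with DE mRNAs whose loci lie
# within a genomic window (default 200 kb), and intersection of those pairs
# with the co-expression network. Distances are nearest-edge gaps between
# transcript intervals (0-based half-open), the most inclusive reading of
# "transcribed within a window"; the boundary is inclusive.

#' Genomic distance between two annotated features
#'
#' @param a,b Single rows of a [feature_annotation()] (or lists with
#'   `chromosome`, `start`, `end`).
#' @return `NA` when the chromosomes differ; 0 when the intervals overlap;
#'   otherwise the gap in bp between the nearest interval ends.
#' @export
genomic_distance <- function(a, b) {
  for (f in list(a, b))
    if (is.null(f$chromosome) || is.null(f$start) || is.null(f$end) ||
        is.na(f$start) || is.na(f$end) || f$start >= f$end)
      stop("malformed interval (need chromosome, start < end)")
  if (a$chromosome != b$chromosome) return(NA_real_)
  if (a$start < b$end && b$start < a$end) return(0)
  if (b$start >= a$end) b$start - a$end else a$start - b$end
}

#' Find cis nearby lncRNA-mRNA pairs
#'
#' Pairs every DE lncRNA with every DE mRNA on the same chromosome whose
#' interval lies within `window` bp (inclusive). The relationship label is
#' assigned from the mRNA's position relative to the lncRNA *on the lncRNA's
#' strand*: an mRNA on the lncRNA's 3' side is `downstream`, on its 5' side
#' `upstream`, and `overlapping` when the intervals intersect.
#'
#' @param lnc_annotations,mrna_annotations [feature_annotation()] subsets for
#'   the DE lncRNAs and DE mRNAs. Features missing from `de_table` are
#'   skipped with a warning.
#' @param de_table DE table from [call_de()] supplying regulation labels.
#' @param window Window size in bp (default 200000, inclusive).
#' @return Data frame of pairs: `lncRNA`, `mRNA`, `distance`, `relationship`,
#'   `lnc_regulation`, `mrna_regulation`, with attribute `"skipped"` naming
#'   features dropped for lack of a DE record.
#' @export
find_cis_pairs <- function(lnc_annotations, mrna_annotations, de_table,
                           window = 200000) {
  skipped <- character(0)
  keep_known <- function(anno) {
    miss <- !(anno$feature_id %in% de_table$feature_id)
    if (any(miss)) {
      skipped <<- c(skipped, anno$feature_id[miss])
      warning("features missing from de_table skipped: ",
              paste(anno$feature_id[miss], collapse = ", "))
    }
    anno[!miss, , drop = FALSE]
  }
  lnc <- keep_known(as.data.frame(lnc_annotations))
  mrna <- keep_known(as.data.frame(mrna_annotations))
  reg <- stats::setNames(de_table$direction, de_table$feature_id)
  rows <- list()
  for (i in seq_len(nrow(lnc))) {
    la <- lnc[i, ]
    same_chr <- mrna[mrna$chromosome == la$chromosome, , drop = FALSE]
    if (!nrow(same_chr)) next
    overlap <- la$start < same_chr$end & same_chr$start < la$end
    gap_right <- same_chr$start - la$end   # mRNA to the genomic right
    gap_left <- la$start - same_chr$end
    dist <- ifelse(overlap, 0, pmax(gap_right, gap_left))
    hit <- dist <= window
    if (!any(hit)) next
    hm <- same_chr[hit, , drop = FALSE]
    right_of <- gap_right[hit] >= 0 & !overlap[hit]
    relationship <- ifelse(overlap[hit], "overlapping",
      ifelse(xor(right_of, la$strand == "-"), "downstream", "upstream"))
    rows[[length(rows) + 1L]] <- data.frame(
      lncRNA = la$feature_id, mRNA = hm$feature_id,
      distance = dist[hit], relationship = relationship,
      lnc_regulation = unname(reg[la$feature_id]),
      mrna_regulation = unname(reg[hm$feature_id]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    lncRNA = character(0), mRNA = character(0), distance = numeric(0),
    relationship = character(0), lnc_regulation = character(0),
    mrna_regulation = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$lncRNA, out$mRNA), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Intersect co-expression edges with cis pairs
#'
#' Exact key intersection on (lncRNA, mRNA); the result carries both the
#' correlation from the CNC edge and the genomic distance from the cis pair.
#'
#' @param cnc_edges Edge data frame from [build_cnc()].
#' @param cis_pairs Pair data frame from [find_cis_pairs()].
#' @return Data frame `lncRNA`, `mRNA`, `r`, `p`, `sign`, `distance`,
#'   `relationship`.
#' @export
intersect_networks <- function(cnc_edges, cis_pairs) {
  out <- merge(cnc_edges, cis_pairs[, c("lncRNA", "mRNA", "distance",
                                        "relationship")],
               by = c("lncRNA", "mRNA"))
  out <- out[order(out$lncRNA, out$mRNA), , drop = FALSE]
  rownames(out) <- NULL
  out
}
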