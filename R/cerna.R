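# ceRNA (lncRNA-miRNA-mRNA) triad inference built on a canonical miRNA
# seed-match engine. A site is a transcript match to the reverse complement
# of the miRNA seed (nucleotides 2-8 of the mature sequence), graded with
# the standard taxonomy:
#
#   8mer     match to nt 2-8 (m8 pairing) plus an A opposite nt 1
#   7mer-m8  match to nt 2-8 (m8 pairing), no A1
#   7mer-A1  match to nt 2-7 plus an A opposite nt 1
#   6mer     match to nt 2-7 only
#
# On the target written 5'->3' the site reads [m8][core 6mer][A1], where the
# core 6mer is the reverse complement of miRNA nt 2-7. No free-energy
# scoring or conservation weighting is attempted: seed matching is the
# reproducible core that target-prediction engines share.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string (U is normalized to T first)
#' @param seq Character scalar over ACGTUN (case-insensitive).
#' @export
reverse_complement <- function(seq) {
  s <- gsub("U", "T", toupper(seq), fixed = TRUE)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (!all(ch %in% names(COMPLEMENT))) stop("illegal nucleotide in sequence")
  paste(rev(unname(COMPLEMENT[ch])), collapse = "")
}

#' Build a miRNA table from mature names and sequences
#'
#' Parses the numeric id from the first integer following `miR-` in the name
#' (`hsa-miR-21-5p` -> 21); names without one (e.g. the let- family) get
#' `NA`. The seed is nucleotides 2-8 of the mature sequence.
#'
#' @param names Character vector of mature miRNA names.
#' @param sequences Mature sequences (RNA or DNA alphabet), length >= 8.
#' @return Data frame `name`, `numeric_id`, `sequence`, `seed`.
#' @export
mirna_table <- function(names, sequences) {
  if (length(names) != length(sequences)) stop("length mismatch")
  seqs <- gsub("U", "T", toupper(sequences), fixed = TRUE)
  if (any(nchar(seqs) < 8L)) stop("mature miRNA sequences must be >= 8 nt")
  m <- regmatches(names, regexpr("miR-([0-9]+)", names))
  ids <- rep(NA_integer_, length(names))
  has <- grepl("miR-[0-9]+", names)
  ids[has] <- as.integer(sub("miR-", "", m))
  data.frame(name = names, numeric_id = ids, sequence = seqs,
             seed = substr(seqs, 2L, 8L), stringsAsFactors = FALSE)
}

#' Filter miRNAs by their numeric id
#'
#' Retains miRNAs with parsed id strictly below `max_id`; names without a
#' parsable miR number (let- family and friends) are retained with a
#' warning, since the id convention does not cover them.
#'
#' @param mirnas Data frame from [mirna_table()].
#' @param max_id Strict upper bound (default 1000).
#' @export
filter_mirnas_by_id <- function(mirnas, max_id = 1000L) {
  unparsed <- is.na(mirnas$numeric_id)
  if (any(unparsed))
    warning("retaining miRNAs without a parsable miR number: ",
            paste(mirnas$name[unparsed], collapse = ", "))
  mirnas[unparsed | mirnas$numeric_id < max_id, , drop = FALSE]
}

#' Find canonical seed sites of one miRNA on one transcript
#'
#' Scans the transcript (5'->3', ACGT alphabet after normalization) for
#' matches to the reverse complement of the miRNA 6mer core (nt 2-7), then
#' grades each match by m8 pairing and the A1 anchor; every core match
#' yields exactly one site with its maximal classification. Windows
#' containing an ambiguous base never match. `start` is the 0-based offset
#' of the 6mer core on the transcript.
#'
#' @param transcript Transcript sequence (character scalar, length >= 6).
#' @param mirna One-row data frame from [mirna_table()] (or a list with
#'   `name` and `sequence`).
#' @param transcript_id Id recorded in the output.
#' @return Data frame `transcript_id`, `mirna`, `start`, `site_type`.
#' @export
find_seed_sites <- function(transcript, mirna, transcript_id = "transcript") {
  tx <- gsub("U", "T", toupper(transcript), fixed = TRUE)
  if (nchar(tx) < 6L) stop("transcript must be >= 6 nt")
  if (grepl("[^ACGTN]", tx)) stop("illegal character in transcript")
  mseq <- gsub("U", "T", toupper(mirna$sequence), fixed = TRUE)
  core <- reverse_complement(substr(mseq, 2L, 7L))        # 6mer core target
  m8 <- unname(COMPLEMENT[substr(mseq, 8L, 8L)])          # base 5' of core
  n <- nchar(tx)
  starts <- seq_len(n - 5L)
  windows <- substring(tx, starts, starts + 5L)
  hit <- which(windows == core)
  if (!length(hit))
    return(data.frame(transcript_id = character(0), mirna = character(0),
                      start = integer(0), site_type = character(0),
                      stringsAsFactors = FALSE))
  has_m8 <- hit > 1L & substring(tx, hit - 1L, hit - 1L) == m8
  has_a1 <- hit + 6L <= n & substring(tx, hit + 6L, hit + 6L) == "A"
  type <- ifelse(has_m8 & has_a1, "8mer",
          ifelse(has_m8, "7mer-m8",
          ifelse(has_a1, "7mer-A1", "6mer")))
  data.frame(transcript_id = transcript_id, mirna = mirna$name,
             start = hit - 1L, site_type = type, stringsAsFactors = FALSE)
}

#' Scan many transcripts against many miRNAs
#'
#' @param transcripts Named character vector (id -> sequence), e.g. from
#'   [read_fasta()].
#' @param mirnas Data frame from [mirna_table()].
#' @return Site table: one row per (transcript, miRNA, position) site.
#' @export
scan_seed_sites <- function(transcripts, mirnas) {
  rows <- list()
  for (i in seq_len(nrow(mirnas))) {
    mi <- mirnas[i, ]
    for (id in names(transcripts)) {
      s <- find_seed_sites(transcripts[[id]], mi, transcript_id = id)
      if (nrow(s)) rows[[length(rows) + 1L]] <- s
    }
  }
  if (!length(rows))
    return(data.frame(transcript_id = character(0), mirna = character(0),
                      start = integer(0), site_type = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build ceRNA triads from shared miRNA sites
#'
#' A triad (lncRNA, miRNA, mRNA) is emitted when both transcripts carry at
#' least `min_sites` seed sites for the miRNA and -- by default -- share the
#' same DE direction, the concordance ceRNA theory requires (a sponge and
#' its protected target co-vary). Setting `require_same_direction = FALSE`
#' drops the concordance gate.
#'
#' @param lnc_sites,mrna_sites Site tables from [scan_seed_sites()] for the
#'   lncRNA and mRNA transcripts respectively.
#' @param de_table DE table from [call_de()]; every transcript appearing in
#'   a site table must have a record.
#' @param require_same_direction Keep only direction-concordant triads
#'   (default `TRUE`).
#' @param min_sites Minimum sites per transcript-miRNA pair (default 1).
#' @return Data frame `lncRNA`, `mirna`, `mRNA`, `lnc_site_count`,
#'   `mrna_site_count`, `lnc_direction`, `mrna_direction`,
#'   `shared_direction` (`NA` when discordant pairs are allowed through),
#'   with attribute `"network_counts"`.
#' @export
build_cerna <- function(lnc_sites, mrna_sites, de_table,
                        require_same_direction = TRUE, min_sites = 1L) {
  all_tx <- unique(c(lnc_sites$transcript_id, mrna_sites$transcript_id))
  miss <- setdiff(all_tx, de_table$feature_id)
  if (length(miss))
    stop("transcripts absent from de_table: ", paste(miss, collapse = ", "))
  dir <- stats::setNames(de_table$direction, de_table$feature_id)
  count_pairs <- function(sites) {
    if (!nrow(sites))
      return(data.frame(transcript_id = character(0), mirna = character(0),
                        n = integer(0), stringsAsFactors = FALSE))
    agg <- stats::aggregate(list(n = sites$start),
                            by = list(transcript_id = sites$transcript_id,
                                      mirna = sites$mirna), FUN = length)
    agg[agg$n >= min_sites, , drop = FALSE]
  }
  lp <- count_pairs(lnc_sites)
  mp <- count_pairs(mrna_sites)
  merged <- merge(lp, mp, by = "mirna", suffixes = c("_lnc", "_mrna"))
  if (!nrow(merged))
    return(empty_triads())
  out <- data.frame(
    lncRNA = merged$transcript_id_lnc, mirna = merged$mirna,
    mRNA = merged$transcript_id_mrna,
    lnc_site_count = merged$n_lnc, mrna_site_count = merged$n_mrna,
    lnc_direction = unname(dir[merged$transcript_id_lnc]),
    mrna_direction = unname(dir[merged$transcript_id_mrna]),
    stringsAsFactors = FALSE)
  if (require_same_direction)
    out <- out[out$lnc_direction == out$mrna_direction, , drop = FALSE]
  out$shared_direction <- ifelse(out$lnc_direction == out$mrna_direction,
                                 out$lnc_direction, NA_character_)
  out <- out[order(out$lncRNA, out$mirna, out$mRNA), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "network_counts") <- list(
    n_lncRNA = length(unique(out$lncRNA)),
    n_miRNA = length(unique(out$mirna)),
    n_mRNA = length(unique(out$mRNA)),
    n_triads = nrow(out))
  out
}

empty_triads <- function() {
  out <- data.frame(lncRNA = character(0), mirna = character(0),
                    mRNA = character(0), lnc_site_count = integer(0),
                    mrna_site_count = integer(0),
                    lnc_direction = character(0),
                    mrna_direction = character(0),
                    shared_direction = character(0), stringsAsFactors = FALSE)
  attr(out, "network_counts") <- list(n_lncRNA = 0L, n_miRNA = 0L,
                                      n_mRNA = 0L, n_triads = 0L)
  out
}

#' Restrict triads to mRNAs annotated in allowed gene sets
#'
#' @param triads Triad table from [build_cerna()].
#' @param gene_sets Gene-set list from [read_gmt()].
#' @param allowed_set_ids Set ids (must exist in `gene_sets`).
#' @param symbols Optional named vector mapping mRNA feature id to gene
#'   symbol; defaults to the identity mapping.
#' @return The triads whose mRNA symbol belongs to at least one allowed set.
#' @export
pathway_restrict <- function(triads, gene_sets, allowed_set_ids,
                             symbols = NULL) {
  unknown <- setdiff(allowed_set_ids, names(gene_sets))
  if (length(unknown))
    stop("unknown gene set id: ", paste(unknown, collapse = ", "))
  if (!length(allowed_set_ids)) return(triads[0, , drop = FALSE])
  allowed_genes <- unique(unlist(lapply(gene_sets[allowed_set_ids],
                                        `[[`, "members")))
  sym <- if (is.null(symbols)) triads$mRNA
         else unname(symbols[triads$mRNA])
  triads[!is.na(sym) & sym %in% allowed_genes, , drop = FALSE]
}
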