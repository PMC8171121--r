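# Shared fixture builders. Everything is generated in code; no binary data.

# Small bundle with explicit values/flags.
tiny_bundle <- function(values, flags = NULL, scale = "linear",
                        feature_prefix = "F", sample_prefix = "S") {
  v <- as.matrix(values)
  ok <- function(nm) !is.null(nm) && !anyDuplicated(nm) && all(nzchar(nm))
  if (!ok(rownames(v))) rownames(v) <- paste0(feature_prefix, seq_len(nrow(v)))
  if (!ok(colnames(v))) colnames(v) <- paste0(sample_prefix, seq_len(ncol(v)))
  if (!is.null(flags)) {
    flags <- matrix(flags, nrow(v), ncol(v), byrow = TRUE)
  }
  expression_bundle(v, flags, scale = scale)
}

# Random positive linear-scale bundle.
random_bundle <- function(n_feat, n_samp, seed = 1) {
  set.seed(seed)
  v <- matrix(2^rnorm(n_feat * n_samp, 8, 1.5), n_feat, n_samp,
              dimnames = list(sprintf("F%03d", seq_len(n_feat)),
                              sprintf("S%d", seq_len(n_samp))))
  expression_bundle(v)
}

# 4-vs-4 design over a bundle's samples.
design44 <- function(bundle) {
  s <- colnames(bundle$values)
  group_design(s, rep(c("case", "control"), each = length(s) / 2))
}

# Minimal annotation row for genomic_distance tests.
interval <- function(chrom, start, end, strand = "+", id = "x",
                     biotype = "mRNA") {
  list(feature_id = id, gene_symbol = id, biotype = biotype,
       chromosome = chrom, strand = strand, start = start, end = end)
}

# Independent brute-force hypergeometric tail: P(X >= k).
hyper_tail_oracle <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Independent window-by-window seed-site classifier (enumeration oracle).
seed_sites_oracle <- function(tx, mirna_name, mirna_seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  tx <- gsub("U", "T", toupper(tx))
  ms <- gsub("U", "T", toupper(mirna_seq))
  core <- rc(substr(ms, 2, 7))
  m8b <- comp[[substr(ms, 8, 8)]]
  out <- NULL
  for (i in seq_len(nchar(tx) - 5)) {
    if (substr(tx, i, i + 5) != core) next
    m8 <- i > 1 && substr(tx, i - 1, i - 1) == m8b
    a1 <- i + 6 <= nchar(tx) && substr(tx, i + 6, i + 6) == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8"
            else if (a1) "7mer-A1" else "6mer"
    out <- rbind(out, data.frame(transcript_id = "tx", mirna = mirna_name,
                                 start = i - 1L, site_type = type,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(transcript_id = character(0), mirna = character(0),
                      start = integer(0), site_type = character(0),
                      stringsAsFactors = FALSE)
  out
}

# PPI edge-table builders.
ppi_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(protein_a = m[, 1], protein_b = m[, 2],
             combined_score = as.numeric(m[, 3]), stringsAsFactors = FALSE)
}

clique_edges <- function(members, score = 0.9) {
  cmb <- combn(members, 2)
  data.frame(protein_a = cmb[1, ], protein_b = cmb[2, ],
             combined_score = score, stringsAsFactors = FALSE)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
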