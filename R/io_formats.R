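# Readers/writers for every external representation the pipeline touches:
# expression matrices with detection flags, feature annotation, group designs,
# GMT gene sets, FASTA sequences, PPI edge tables and TSV/SIF edge exports.
# All genomic coordinates are stored 0-based half-open (BED convention);
# 1-based input dialects are converted at the reader boundary.

VALID_FLAGS <- c("P", "M", "A")

#' Construct an expression bundle
#'
#' An expression bundle is the raw substrate of every pipeline stage: a
#' feature-by-sample intensity matrix paired with per-cell detection flags
#' (Present / Marginal / Absent) and a scale marker.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   unique row and column names. Linear-scale intensities must be
#'   non-negative; log2-scale values may be any real.
#' @param flags Character matrix of identical shape, entries in
#'   `c("P", "M", "A")` (full-word spellings `Present`/`Marginal`/`Absent`
#'   are normalized).
#' @param scale Either `"linear"` or `"log2"`.
#' @return An object of class `expression_bundle`: a list with elements
#'   `values`, `flags`, `scale`.
#' @export
expression_bundle <- function(values, flags = NULL, scale = "linear") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry feature (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (anyNA(values))
    stop("missing intensity values are not allowed (no imputation is performed)")
  scale <- match.arg(scale, c("linear", "log2"))
  if (scale == "linear" && any(values < 0))
    stop("linear-scale intensities must be non-negative")
  if (is.null(flags)) {
    flags <- matrix("P", nrow(values), ncol(values), dimnames = dimnames(values))
  } else {
    if (!is.matrix(flags) || !identical(dim(flags), dim(values)))
      stop("`flags` must be a matrix with the same shape as `values`")
    flags <- normalize_flags(flags)
    dimnames(flags) <- dimnames(values)
  }
  structure(list(values = values, flags = flags, scale = scale),
            class = "expression_bundle")
}

normalize_flags <- function(flags) {
  x <- toupper(as.character(flags))
  x[x %in% c("PRESENT")] <- "P"
  x[x %in% c("MARGINAL")] <- "M"
  x[x %in% c("ABSENT")] <- "A"
  bad <- !(x %in% VALID_FLAGS)
  if (any(bad)) {
    idx <- which(bad)[1L]
    dm <- arrayInd(idx, dim(flags))
    stop(sprintf("unknown detection flag '%s' at feature row %d, sample column %d",
                 as.character(flags)[idx], dm[1L], dm[2L]))
  }
  matrix(x, nrow(flags), ncol(flags))
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat(sprintf("<expression_bundle> %d features x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expression_bundle <- function(x) dim(x$values)

#' Read a tab-delimited expression matrix with detection flags
#'
#' Expected schema: a header row; first column the feature id; for every
#' sample `<s>` an intensity column named `<s>` and a flag column named
#' `<s><flag_suffix>`. Feature order of the file is preserved.
#'
#' @param path File path.
#' @param flag_suffix Suffix identifying flag columns (default `"_flag"`).
#' @param scale Scale of the stored intensities.
#' @return An [expression_bundle()].
#' @export
read_expression <- function(path, flag_suffix = "_flag", scale = "linear") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3L) stop("expression file needs a feature column plus value/flag pairs")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate feature id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cols <- names(df)[-1L]
  flag_cols <- grep(paste0(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", flag_suffix), "$"),
                    cols, value = TRUE)
  val_cols <- setdiff(cols, flag_cols)
  expected_flags <- paste0(val_cols, flag_suffix)
  if (!setequal(flag_cols, expected_flags))
    stop("flag columns do not pair with sample columns (expected one '",
         flag_suffix, "' column per sample)")
  vals <- matrix(NA_real_, length(ids), length(val_cols),
                 dimnames = list(ids, val_cols))
  for (j in seq_along(val_cols)) {
    v <- suppressWarnings(as.numeric(df[[val_cols[j]]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("non-numeric intensity '%s' at row %d, column '%s'",
                   df[[val_cols[j]]][i], i, val_cols[j]))
    }
    vals[, j] <- v
  }
  fl <- as.matrix(df[, expected_flags, drop = FALSE])
  expression_bundle(vals, fl, scale = scale)
}

#' Write an expression bundle to a tab-delimited file
#'
#' Inverse of [read_expression()]; intensities are serialized at full double
#' precision so a write/read round trip is exact.
#'
#' @param bundle An [expression_bundle()].
#' @param path Output path.
#' @param flag_suffix Flag column suffix.
#' @export
write_expression <- function(bundle, path, flag_suffix = "_flag") {
  stopifnot(inherits(bundle, "expression_bundle"))
  v <- bundle$values
  out <- data.frame(feature_id = rownames(v), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(v))) {
    out[[colnames(v)[j]]] <- sprintf("%.17g", v[, j])
    out[[paste0(colnames(v)[j], flag_suffix)]] <- bundle$flags[, j]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a feature annotation table
#'
#' @param df Data frame with columns `feature_id`, `gene_symbol`, `biotype`
#'   (`lncRNA` or `mRNA`), `chromosome`, `strand` (`+`/`-`), `start`, `end`.
#'   Coordinates are 0-based half-open.
#' @return The validated data frame (class `feature_annotation` prepended).
#' @export
feature_annotation <- function(df) {
  need <- c("feature_id", "gene_symbol", "biotype", "chromosome",
            "strand", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$feature_id)) stop("duplicate feature_id in annotation")
  if (!all(df$biotype %in% c("lncRNA", "mRNA")))
    stop("biotype must be 'lncRNA' or 'mRNA'")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  if (any(df$start >= df$end)) stop("annotation intervals must satisfy start < end")
  class(df) <- c("feature_annotation", class(df))
  df
}

#' Read a feature annotation TSV (0-based half-open coordinates)
#' @param path File path.
#' @param one_based If `TRUE` the file stores 1-based inclusive coordinates,
#'   converted on read.
#' @export
read_annotation <- function(path, one_based = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (one_based) {
    df$start <- df$start - 1L
  }
  feature_annotation(df)
}

#' Construct a two-group design
#'
#' @param sample_ids Character vector of sample ids.
#' @param groups Character vector of equal length with labels `"case"` /
#'   `"control"` (case = the condition of interest, e.g. POD).
#' @return Data frame `sample_id`, `group` (class `group_design`).
#' @export
group_design <- function(sample_ids, groups) {
  if (length(sample_ids) != length(groups)) stop("length mismatch")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in design")
  if (!all(groups %in% c("case", "control")))
    stop("groups must be 'case' or 'control'")
  tb <- table(factor(groups, levels = c("case", "control")))
  if (any(tb < 2L)) stop("each group needs at least 2 samples")
  structure(data.frame(sample_id = sample_ids, group = groups,
                       stringsAsFactors = FALSE),
            class = c("group_design", "data.frame"))
}

#' Read a two-column design TSV (sample_id, group)
#' @param path File path.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  group_design(df$sample_id, df$group)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-delimited
#' `set_id <TAB> description <TAB> member1 <TAB> member2 ...`.
#' The description field doubles as the category when it is one of
#' `BP`, `CC`, `MF`, `pathway`; otherwise category is `"pathway"`.
#'
#' @param path File path.
#' @return A named list of gene sets; each element is a list with `set_id`,
#'   `name`, `category`, `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d fields; at least 3 required", i, length(f)))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop(sprintf("GMT line %d has no members", i))
    cat_tok <- if (f[2L] %in% c("BP", "CC", "MF", "pathway")) f[2L] else "pathway"
    sets[[i]] <- list(set_id = f[1L], name = f[2L], category = cat_tok,
                      members = members)
  }
  ids <- vapply(sets, `[[`, "", "set_id")
  if (anyDuplicated(ids)) stop("duplicate set id in GMT: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(sets) <- ids
  sets
}

#' Write gene sets to a GMT file
#' @param sets List as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$set_id, s$name, s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a nucleotide FASTA file
#'
#' Ids are the first whitespace-delimited token of the header; `U` is
#' normalized to `T` so downstream seed matching works on one alphabet.
#'
#' @param path File path.
#' @return Named character vector id -> sequence (possibly empty).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("FASTA must start with a '>' header")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), "")
  out <- stats::setNames(rep("", length(ids)), ids)
  out[as.integer(names(seqs))] <- seqs
  names(out) <- ids
  out <- toupper(out)
  out <- gsub("U", "T", out, fixed = TRUE)
  bad <- grepl("[^ACGTN]", out)
  if (any(bad))
    stop("illegal character in sequence of '", ids[which(bad)[1L]], "'")
  out
}

#' Write named sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    if (nchar(s)) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Read a STRING-export-like PPI edge table
#'
#' Tab-delimited with header columns `protein_a`, `protein_b`,
#' `combined_score` (in [0,1]). Self-loops are dropped on load.
#'
#' @param path File path.
#' @export
read_ppi_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("protein_a", "protein_b", "combined_score")
  if (!all(need %in% names(df)))
    stop("PPI table must have columns: ", paste(need, collapse = ", "))
  df$combined_score <- as.numeric(df$combined_score)
  if (anyNA(df$combined_score)) stop("non-numeric combined_score in PPI table")
  if (any(df$combined_score < 0 | df$combined_score > 1))
    stop("combined_score must lie in [0, 1]")
  df[df$protein_a != df$protein_b, need, drop = FALSE]
}

#' Write an edge table deterministically (TSV or SIF)
#'
#' Rows are sorted by source then target id so re-running on the same content
#' yields a byte-identical file. For SIF, `interaction` (or a per-edge
#' `interaction` column) supplies the relationship token.
#'
#' @param edges Data frame whose first two columns are source and target ids.
#' @param path Output path.
#' @param dialect `"tsv"` or `"sif"`.
#' @param interaction Default interaction token for SIF output.
#' @export
write_edge_table <- function(edges, path, dialect = c("tsv", "sif"),
                             interaction = "interacts") {
  dialect <- match.arg(dialect)
  edges <- as.data.frame(edges)
  if (nrow(edges))
    edges <- edges[order(edges[[1L]], edges[[2L]]), , drop = FALSE]
  if (dialect == "tsv") {
    num <- vapply(edges, is.double, TRUE)
    edges[num] <- lapply(edges[num], function(x) sprintf("%.17g", x))
    utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    tok <- if ("interaction" %in% names(edges)) edges$interaction
           else rep(interaction, nrow(edges))
    writeLines(paste(edges[[1L]], tok, edges[[2L]]), path)
  }
  invisible(path)
}
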