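# Seeded synthetic-study generator with planted ground truth.
#
# The generator emulates a small two-group (4 vs 4) one-color lncRNA/mRNA
# array experiment: log-normal probe intensities (baseline log2 level per
# feature, i.i.d. Gaussian measurement noise), a minority of features with
# planted group shifts of at least 1.5-fold, dedicated lncRNA-mRNA pairs
# sharing a latent profile calibrated to a target Pearson correlation,
# cis neighbours placed at controlled gaps straddling the 200-kb window,
# transcripts seeded with exact miRNA 8mer target sites, a PPI edge table
# with planted dense modules, and detection-flag patterns exercising the
# flag filter. All randomness flows from the single mandatory seed.

#' Simulation configuration
#'
#' Defaults state the emulated world: 4 cases vs 4 controls; log2 baseline
#' N(8, 1.5); measurement noise sd 0.25 on the log2 scale; 10% of features
#' DE with linear fold changes log-uniform on [1.5, 4]; 30 planted
#' co-expression pairs at target |r| = 0.95 (one quarter negative); cis
#' neighbours at gaps 50/150/200/250 kb bracketing the window boundary;
#' 10-nt-seeded miRNA triads on 500-nt transcripts.
#'
#' @param seed Mandatory integer seed.
#' @param n_case,n_control Group sizes.
#' @param n_lncrna,n_mrna Feature counts per biotype.
#' @param frac_de Fraction of features with a planted group shift.
#' @param fc_range Linear fold-change range for planted shifts (log-uniform).
#' @param noise_sd Measurement noise sd (log2 scale).
#' @param baseline_mean,baseline_sd Distribution of per-feature baseline
#'   log2 levels.
#' @param n_coexpr_pairs Planted lncRNA-mRNA co-expression pairs.
#' @param coexpr_r Target |Pearson r| of planted pairs (population value via
#'   the latent-loading closed form).
#' @param frac_coexpr_negative Fraction of planted pairs with negative sign.
#' @param cis_gaps Gaps (bp) at which cis neighbours are planted.
#' @param n_cis_per_gap Planted pairs per gap value.
#' @param n_mirnas miRNAs generated (ids bracket the 1000 cutoff).
#' @param n_triads Planted (lncRNA, miRNA, mRNA) triads.
#' @param transcript_length Length of generated transcript sequences (nt).
#' @param n_ppi_genes Genes in the PPI background.
#' @param ppi_background_p Erdos-Renyi background edge probability.
#' @param ppi_module_sizes Sizes of planted near-clique PPI modules.
#' @param frac_absent Fraction of features given an undetected (Absent)
#'   flag pattern, to be removed by the flag filter.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_case = 4L, n_control = 4L,
                              n_lncrna = 1200L, n_mrna = 2800L,
                              frac_de = 0.10, fc_range = c(1.5, 4),
                              noise_sd = 0.25,
                              baseline_mean = 8, baseline_sd = 1.5,
                              n_coexpr_pairs = 30L, coexpr_r = 0.95,
                              frac_coexpr_negative = 0.25,
                              cis_gaps = c(5e4, 1.5e5, 2e5, 2.5e5),
                              n_cis_per_gap = 2L,
                              n_mirnas = 10L, n_triads = 10L,
                              transcript_length = 500L,
                              n_ppi_genes = 60L, ppi_background_p = 0.02,
                              ppi_module_sizes = c(6L, 7L),
                              frac_absent = 0.05) {
  if (missing(seed)) stop("`seed` is mandatory")
  cfg <- as.list(environment())
  if (cfg$coexpr_r <= 0 || cfg$coexpr_r >= 1)
    stop("coexpr_r must lie in (0, 1)")
  counts <- unlist(cfg[c("n_case", "n_control", "n_lncrna", "n_mrna",
                         "n_coexpr_pairs", "n_cis_per_gap", "n_mirnas",
                         "n_triads")])
  if (any(counts < 0)) stop("counts must be non-negative")
  needed <- cfg$n_coexpr_pairs + cfg$n_triads +
    length(cfg$cis_gaps) * cfg$n_cis_per_gap
  if (needed > cfg$n_lncrna ||
      needed + sum(cfg$ppi_module_sizes) > cfg$n_mrna)
    stop("more planted pairs/triads than available features")
  class(cfg) <- "simulation_config"
  cfg
}

random_seq <- function(n_char) {
  paste(sample(c("A", "C", "G", "T"), n_char, replace = TRUE), collapse = "")
}

#' Generate a complete synthetic study with ground truth
#'
#' @param config A [simulation_config()].
#' @return List with `bundle` (linear-scale [expression_bundle()]),
#'   `annotation`, `design`, `transcripts` (named sequences for DE-relevant
#'   features), `mirnas` ([mirna_table()]), `ppi_edges`, `gene_sets`, and
#'   `truth` (planted DE features, co-expression pairs, cis pairs, triads,
#'   PPI modules, undetected features).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_feat <- config$n_lncrna + config$n_mrna
  n_samp <- config$n_case + config$n_control
  lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lncrna))
  mrna_ids <- sprintf("MRNA%04d", seq_len(config$n_mrna))
  ids <- c(lnc_ids, mrna_ids)
  biotype <- c(rep("lncRNA", config$n_lncrna), rep("mRNA", config$n_mrna))
  samples <- c(sprintf("CASE%d", seq_len(config$n_case)),
               sprintf("CTRL%d", seq_len(config$n_control)))
  design <- group_design(samples, c(rep("case", config$n_case),
                                    rep("control", config$n_control)))
  case_cols <- seq_len(config$n_case)

  # --- reserve disjoint feature blocks for each planted structure ---------
  n_cis <- length(config$cis_gaps) * config$n_cis_per_gap
  take <- function(pool, k) {
    if (k == 0L) return(list(got = pool[0L], rest = pool))
    list(got = pool[seq_len(k)], rest = pool[-seq_len(k)])
  }
  lp <- take(lnc_ids, config$n_coexpr_pairs)
  coexpr_lnc <- lp$got; lnc_rest <- lp$rest
  lp <- take(lnc_rest, n_cis); cis_lnc <- lp$got; lnc_rest <- lp$rest
  lp <- take(lnc_rest, config$n_triads); triad_lnc <- lp$got; lnc_rest <- lp$rest
  mp <- take(mrna_ids, config$n_coexpr_pairs)
  coexpr_mrna <- mp$got; mrna_rest <- mp$rest
  mp <- take(mrna_rest, n_cis); cis_mrna <- mp$got; mrna_rest <- mp$rest
  mp <- take(mrna_rest, config$n_triads); triad_mrna <- mp$got; mrna_rest <- mp$rest
  mp <- take(mrna_rest, sum(config$ppi_module_sizes))
  ppi_mod_mrna <- mp$got; mrna_rest <- mp$rest

  # --- planted DE: cis/triad features are always DE (downstream stages
  #     operate on DE features); the remaining DE quota is drawn at random
  forced_de <- c(cis_lnc, cis_mrna, triad_lnc, triad_mrna, ppi_mod_mrna)
  n_de_target <- round(config$frac_de * n_feat)
  free_pool <- setdiff(ids, c(forced_de, coexpr_lnc, coexpr_mrna))
  n_extra <- max(0L, n_de_target - length(forced_de))
  extra_de <- if (n_extra > 0L) sample(free_pool, min(n_extra, length(free_pool)))
              else character(0)
  de_ids <- c(forced_de, extra_de)
  lfc <- stats::runif(length(de_ids), log2(config$fc_range[1L]),
                      log2(config$fc_range[2L]))
  de_dir <- sample(c("up", "down"), length(de_ids), replace = TRUE)
  # triad members must share direction (the ceRNA concordance gate);
  # cis pair directions stay independent, as real nearby-gene tables mix
  names(de_dir) <- names(lfc) <- de_ids
  de_dir[triad_mrna] <- de_dir[triad_lnc]
  # PPI modules live inside one DE direction panel each (alternating)
  mod_dir <- rep(rep_len(c("up", "down"), length(config$ppi_module_sizes)),
                 config$ppi_module_sizes)
  de_dir[ppi_mod_mrna] <- mod_dir

  # --- expression matrix on the log2 scale --------------------------------
  baseline <- stats::rnorm(n_feat, config$baseline_mean, config$baseline_sd)
  names(baseline) <- ids
  logm <- matrix(stats::rnorm(n_feat * n_samp, 0, config$noise_sd),
                 n_feat, n_samp, dimnames = list(ids, samples))
  logm <- logm + baseline
  shift <- ifelse(de_dir == "up", 1, -1) * lfc
  logm[de_ids, case_cols] <- logm[de_ids, case_cols] + shift

  # --- planted co-expression: latent factor x = a z + sqrt(1-a^2) e with
  #     a = sqrt(rho), so cor(x, y) = rho in the population -----------------
  a <- sqrt(config$coexpr_r)
  n_neg <- round(config$frac_coexpr_negative * config$n_coexpr_pairs)
  pair_sign <- rep(c("negative", "positive"),
                   c(n_neg, config$n_coexpr_pairs - n_neg))
  for (i in seq_len(config$n_coexpr_pairs)) {
    z <- stats::rnorm(n_samp)
    e1 <- stats::rnorm(n_samp); e2 <- stats::rnorm(n_samp)
    sgn <- if (pair_sign[i] == "negative") -1 else 1
    logm[coexpr_lnc[i], ] <- baseline[coexpr_lnc[i]] +
      config$noise_sd * (a * z + sqrt(1 - a^2) * e1)
    logm[coexpr_mrna[i], ] <- baseline[coexpr_mrna[i]] +
      config$noise_sd * (sgn * a * z + sqrt(1 - a^2) * e2)
  }

  # --- annotation: cis pairs on a dedicated chromosome, 1 Mb + window apart
  chroms <- sprintf("chr%d", 1:5)
  anno <- data.frame(
    feature_id = ids,
    gene_symbol = c(sprintf("LNCG%04d", seq_len(config$n_lncrna)),
                    sprintf("GENE%04d", seq_len(config$n_mrna))),
    biotype = biotype,
    chromosome = sample(chroms, n_feat, replace = TRUE),
    strand = sample(c("+", "-"), n_feat, replace = TRUE),
    start = round(stats::runif(n_feat, 0, 1e7)),
    stringsAsFactors = FALSE)
  anno$end <- anno$start + round(stats::runif(n_feat, 1000, 10000))
  gaps <- rep(config$cis_gaps, each = config$n_cis_per_gap)
  block <- 2e6  # one block per planted pair, far beyond any window
  for (i in seq_along(cis_lnc)) {
    li <- match(cis_lnc[i], anno$feature_id)
    mi <- match(cis_mrna[i], anno$feature_id)
    anno$chromosome[c(li, mi)] <- "chrS"
    anno$strand[c(li, mi)] <- "+"
    anno$start[li] <- (i - 1) * block
    anno$end[li] <- anno$start[li] + 2000
    anno$start[mi] <- anno$end[li] + gaps[i]
    anno$end[mi] <- anno$start[mi] + 2000
  }
  anno <- feature_annotation(anno)

  # --- miRNAs and transcript sequences with planted 8mer sites ------------
  mirna_ids_num <- sort(sample(c(sample(1:999, max(1L, config$n_mirnas - 2L)),
                                 sample(1000:5000, min(2L, config$n_mirnas)))))
  mirna_names <- sprintf("hsa-miR-%d-5p", mirna_ids_num)
  mirna_seqs <- vapply(seq_along(mirna_names), function(i) random_seq(22L), "")
  mirnas <- mirna_table(mirna_names, mirna_seqs)
  low_id <- mirnas$name[!is.na(mirnas$numeric_id) & mirnas$numeric_id < 1000]
  tx_ids <- unique(c(triad_lnc, triad_mrna, de_ids))
  transcripts <- stats::setNames(
    vapply(tx_ids, function(i) random_seq(config$transcript_length), ""),
    tx_ids)
  triad_mirna <- sample(low_id, config$n_triads, replace = TRUE)
  plant_site <- function(seqs, tx, mir_seq) {
    # 8mer site: [complement of nt8][revcomp nt2-7]["A"], core offset = pos+1
    site <- paste0(reverse_complement(substr(mir_seq, 2L, 8L)), "A")
    pos <- sample(nchar(seqs[[tx]]) - nchar(site) - 2L, 1L) + 1L
    substr(seqs[[tx]], pos, pos + nchar(site) - 1L) <- site
    list(seqs = seqs, core_offset = pos)  # 0-based core = (pos-1) + 1 = pos
  }
  triad_lnc_off <- triad_mrna_off <- integer(config$n_triads)
  for (i in seq_len(config$n_triads)) {
    ms <- mirnas$sequence[mirnas$name == triad_mirna[i]]
    r1 <- plant_site(transcripts, triad_lnc[i], ms)
    transcripts <- r1$seqs; triad_lnc_off[i] <- r1$core_offset
    r2 <- plant_site(transcripts, triad_mrna[i], ms)
    transcripts <- r2$seqs; triad_mrna_off[i] <- r2$core_offset
  }

  # --- flags: Present by default; a slice of non-planted features made
  #     undetected (< half the samples P/M) with floor-level intensities ---
  flags <- matrix("P", n_feat, n_samp, dimnames = list(ids, samples))
  marg <- matrix(stats::runif(n_feat * n_samp) < 0.05, n_feat, n_samp)
  flags[marg] <- "M"
  protected <- c(de_ids, coexpr_lnc, coexpr_mrna)
  absent_pool <- setdiff(ids, protected)
  n_absent <- min(round(config$frac_absent * n_feat), length(absent_pool))
  absent_ids <- if (n_absent > 0L) sample(absent_pool, n_absent) else character(0)
  for (f in absent_ids) {
    n_pm <- sample(0:(ceiling(n_samp / 2) - 1L), 1L)
    row <- c(rep("P", n_pm), rep("A", n_samp - n_pm))
    flags[f, ] <- sample(row)
    logm[f, flags[f, ] == "A"] <- stats::rnorm(sum(flags[f, ] == "A"), 2, 0.5)
  }

  bundle <- expression_bundle(2^logm, flags, scale = "linear")

  # --- PPI edges over mRNA gene symbols with planted near-cliques ---------
  # module genes are DE (so the per-direction PPI panels contain them);
  # the background fills up with other DE then non-DE mRNAs
  sym_of <- function(f) anno$gene_symbol[match(f, anno$feature_id)]
  bg_feat <- utils::head(c(setdiff(intersect(de_ids, mrna_ids), ppi_mod_mrna),
                           mrna_rest),
                         max(0L, config$n_ppi_genes - length(ppi_mod_mrna)))
  ppi_genes <- sym_of(c(ppi_mod_mrna, bg_feat))
  modules <- list()
  cursor <- 1L
  edge_rows <- list()
  for (sz in config$ppi_module_sizes) {
    mem <- ppi_genes[cursor:(cursor + sz - 1L)]
    cursor <- cursor + sz
    cmb <- utils::combn(mem, 2L)
    edge_rows[[length(edge_rows) + 1L]] <- data.frame(
      protein_a = cmb[1L, ], protein_b = cmb[2L, ],
      combined_score = round(stats::runif(ncol(cmb), 0.85, 0.99), 3L),
      stringsAsFactors = FALSE)
    modules[[length(modules) + 1L]] <- mem
  }
  bg <- ppi_genes[cursor:length(ppi_genes)]
  cmb <- utils::combn(bg, 2L)
  pick <- stats::runif(ncol(cmb)) < config$ppi_background_p
  if (any(pick))
    edge_rows[[length(edge_rows) + 1L]] <- data.frame(
      protein_a = cmb[1L, pick], protein_b = cmb[2L, pick],
      combined_score = round(stats::runif(sum(pick), 0.15, 0.99), 3L),
      stringsAsFactors = FALSE)
  ppi_edges <- do.call(rbind, edge_rows)
  rownames(ppi_edges) <- NULL

  # --- gene sets: random sets plus one enriched in DE mRNA symbols --------
  sym <- stats::setNames(anno$gene_symbol, anno$feature_id)
  mrna_sym <- unname(sym[mrna_ids])
  de_mrna_sym <- unname(sym[intersect(de_ids, mrna_ids)])
  gene_sets <- list()
  for (i in 1:8) {
    cat_tok <- c("BP", "CC", "MF", "pathway")[(i - 1L) %% 4L + 1L]
    gene_sets[[sprintf("SET%02d", i)]] <- list(
      set_id = sprintf("SET%02d", i), name = cat_tok, category = cat_tok,
      members = sample(mrna_sym, 25L))
  }
  enr_members <- unique(c(sample(de_mrna_sym, min(15L, length(de_mrna_sym))),
                          sample(mrna_sym, 10L)))
  gene_sets[["SET_DE"]] <- list(set_id = "SET_DE", name = "pathway",
                                category = "pathway", members = enr_members)

  truth <- list(
    de = data.frame(feature_id = de_ids, direction = unname(de_dir[de_ids]),
                    fold_change = 2^unname(lfc[de_ids]),
                    stringsAsFactors = FALSE),
    coexpr_pairs = data.frame(lncRNA = coexpr_lnc, mRNA = coexpr_mrna,
                              target_r = rep(config$coexpr_r,
                                             length(coexpr_lnc)),
                              sign = pair_sign, stringsAsFactors = FALSE),
    cis_pairs = data.frame(lncRNA = cis_lnc, mRNA = cis_mrna, gap = gaps,
                           stringsAsFactors = FALSE),
    triads = data.frame(lncRNA = triad_lnc, mirna = triad_mirna,
                        mRNA = triad_mrna, lnc_core_offset = triad_lnc_off,
                        mrna_core_offset = triad_mrna_off,
                        stringsAsFactors = FALSE),
    ppi_modules = modules,
    absent_features = absent_ids,
    seed = config$seed)

  list(bundle = bundle, annotation = anno, design = design,
       transcripts = transcripts, mirnas = mirnas, ppi_edges = ppi_edges,
       gene_sets = gene_sets, truth = truth, config = config)
}

#' Precision/recall of pipeline outputs against planted truth
#'
#' @param truth `truth` element of [simulate_study()] output.
#' @param de_table DE table from [call_de()] (optional).
#' @param cnc_edges Edge table from [build_cnc()] (optional).
#' @param cis_pairs Pair table from [find_cis_pairs()] (optional).
#' @param overlap Overlap table from [intersect_networks()] (optional).
#' @param triads Triad table from [build_cerna()] (optional).
#' @param window Window used for the cis stage (planted pairs beyond it are
#'   not recoverable and excluded from the recall denominator).
#' @return Data frame: one row per evaluated stage with `n_planted`,
#'   `n_recovered`, `recall`, `n_extra` (calls that are not planted).
#' @export
truth_recovery_report <- function(truth, de_table = NULL, cnc_edges = NULL,
                                  cis_pairs = NULL, overlap = NULL,
                                  triads = NULL, window = 200000) {
  rows <- list()
  add <- function(stage, planted_keys, called_keys) {
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, n_planted = length(planted_keys),
      n_recovered = sum(planted_keys %in% called_keys),
      recall = if (length(planted_keys))
        sum(planted_keys %in% called_keys) / length(planted_keys) else NA_real_,
      n_extra = sum(!(called_keys %in% planted_keys)),
      stringsAsFactors = FALSE)
  }
  if (!is.null(de_table)) {
    called <- de_table[de_table$de, ]
    add("de", paste(truth$de$feature_id, truth$de$direction),
        paste(called$feature_id, called$direction))
  }
  if (!is.null(cnc_edges))
    add("cnc", paste(truth$coexpr_pairs$lncRNA, truth$coexpr_pairs$mRNA),
        paste(cnc_edges$lncRNA, cnc_edges$mRNA))
  if (!is.null(cis_pairs)) {
    recoverable <- truth$cis_pairs[truth$cis_pairs$gap <= window, ]
    add("cis", paste(recoverable$lncRNA, recoverable$mRNA),
        paste(cis_pairs$lncRNA, cis_pairs$mRNA))
  }
  if (!is.null(overlap)) {
    joint <- merge(truth$coexpr_pairs, truth$cis_pairs, by = c("lncRNA", "mRNA"))
    joint <- joint[joint$gap <= window, ]
    add("overlap", paste(joint$lncRNA, joint$mRNA),
        paste(overlap$lncRNA, overlap$mRNA))
  }
  if (!is.null(triads))
    add("cerna",
        paste(truth$triads$lncRNA, truth$triads$mirna, truth$triads$mRNA),
        paste(triads$lncRNA, triads$mirna, triads$mRNA))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
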