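# Smaller-than-default configs keep the suite fast; the acceptance file
# exercises the default scale.
small_config <- function(seed, ...) {
  simulation_config(seed = seed, n_lncrna = 150L, n_mrna = 350L, ...)
}

test_that("identical config and seed reproduce identical worlds, file bytes included", {
  s1 <- simulate_study(small_config(7))
  s2 <- simulate_study(small_config(7))
  expect_identical(s1$bundle$values, s2$bundle$values)
  expect_identical(s1$bundle$flags, s2$bundle$flags)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$truth, s2$truth)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression(s1$bundle, f1); write_expression(s2$bundle, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_study(small_config(8))
  expect_false(identical(s1$bundle$values, s3$bundle$values))
})

test_that("planted truth is internally consistent with the generated world", {
  sim <- simulate_study(small_config(11))
  ids <- rownames(sim$bundle$values)
  expect_true(all(sim$truth$de$feature_id %in% ids))
  expect_true(all(sim$truth$de$fold_change >= 1.5))
  expect_true(all(c(sim$truth$coexpr_pairs$lncRNA,
                    sim$truth$cis_pairs$lncRNA,
                    sim$truth$triads$lncRNA) %in% ids))
  # planted cis gaps are exact by construction
  anno <- as.data.frame(sim$annotation)
  for (i in seq_len(nrow(sim$truth$cis_pairs))) {
    la <- anno[anno$feature_id == sim$truth$cis_pairs$lncRNA[i], ]
    ma <- anno[anno$feature_id == sim$truth$cis_pairs$mRNA[i], ]
    expect_equal(genomic_distance(la, ma), sim$truth$cis_pairs$gap[i])
  }
  # undetected features fail the flag filter, planted features survive it
  kept <- rownames(filter_by_flags(sim$bundle, 4)$values)
  expect_length(intersect(sim$truth$absent_features, kept), 0)
  expect_true(all(sim$truth$de$feature_id %in% kept))
  # triad directions concordant by construction
  dirs <- setNames(sim$truth$de$direction, sim$truth$de$feature_id)
  expect_identical(unname(dirs[sim$truth$triads$lncRNA]),
                   unname(dirs[sim$truth$triads$mRNA]))
})

test_that("every planted triad's seed sites re-validate through the site engine", {
  sim <- simulate_study(small_config(13))
  for (i in seq_len(nrow(sim$truth$triads))) {
    tr <- sim$truth$triads[i, ]
    mir <- sim$mirnas[sim$mirnas$name == tr$mirna, ]
    ls <- find_seed_sites(sim$transcripts[[tr$lncRNA]], mir, tr$lncRNA)
    ms <- find_seed_sites(sim$transcripts[[tr$mRNA]], mir, tr$mRNA)
    expect_true(tr$lnc_core_offset %in% ls$start)
    expect_true(tr$mrna_core_offset %in% ms$start)
    expect_identical(ls$site_type[ls$start == tr$lnc_core_offset], "8mer")
  }
})

test_that("planted DE shifts are recovered with high sensitivity and direction", {
  sim <- simulate_study(small_config(17))
  norm <- preprocess(sim$bundle)$bundle
  de <- call_de(norm, sim$design, sim$annotation)
  rep <- truth_recovery_report(sim$truth, de_table = de)
  expect_gt(rep$recall[rep$stage == "de"], 0.9)
  # oracle check of the report arithmetic itself
  called <- paste(de$feature_id[de$de], de$direction[de$de])
  planted <- paste(sim$truth$de$feature_id, sim$truth$de$direction)
  expect_identical(rep$n_recovered[1], sum(planted %in% called))
  expect_identical(rep$n_extra[1], sum(!(called %in% planted)))
})

test_that("latent-factor calibration hits the target correlation in the mean", {
  rs <- unlist(lapply(1:6, function(s) {
    sim <- simulate_study(small_config(s))
    logm <- log2(sim$bundle$values)
    tp <- sim$truth$coexpr_pairs
    mapply(function(l, m) abs(cor(logm[l, ], logm[m, ])), tp$lncRNA, tp$mRNA)
  }))
  expect_lt(abs(mean(rs) - 0.95), 0.03)
})

test_that("infeasible and degenerate configs are handled", {
  expect_error(simulation_config(seed = 1, n_lncrna = 10L, n_mrna = 10L),
               "more planted")
  expect_error(simulation_config(), "mandatory")
  expect_error(simulation_config(seed = 1, coexpr_r = 1.2), "\\(0, 1\\)")
  # zero planted effects: a pure null world
  nullcfg <- simulation_config(seed = 3, n_lncrna = 100L, n_mrna = 200L,
                               frac_de = 0, n_coexpr_pairs = 0L,
                               n_cis_per_gap = 0L, n_triads = 0L,
                               ppi_module_sizes = integer(0),
                               frac_absent = 0)
  sim <- simulate_study(nullcfg)
  expect_identical(nrow(sim$truth$de), 0L)
  de <- call_de(log2_transform(sim$bundle), sim$design, sim$annotation)
  expect_lt(mean(de$p_value < 0.05), 0.12)  # loose sanity; exact size in acceptance
})

test_that("planted PPI modules are recovered per direction panel", {
  sim <- simulate_study(small_config(23))
  dirs <- setNames(sim$truth$de$direction, sim$truth$de$feature_id)
  anno <- as.data.frame(sim$annotation)
  sym <- setNames(anno$gene_symbol, anno$feature_id)
  for (i in seq_along(sim$truth$ppi_modules)) {
    mod <- sim$truth$ppi_modules[[i]]
    feat <- anno$feature_id[match(mod, anno$gene_symbol)]
    dirn <- unique(unname(dirs[feat]))
    expect_length(dirn, 1)                      # whole module in one panel
    universe <- unname(sym[names(dirs)[dirs == dirn]])
    g <- build_ppi(sim$ppi_edges, universe)
    smin <- if (dirn == "up") 4 else 5
    cls <- mcode_clusters(g, score_min = smin)
    expect_true(any(vapply(cls, function(cl) all(mod %in% cl$members), TRUE)))
  }
})

test_that("cis neighbours beyond the window are never recovered", {
  sim <- simulate_study(small_config(19))
  anno <- as.data.frame(sim$annotation)
  truth_cis <- sim$truth$cis_pairs
  de <- data.frame(feature_id = sim$truth$de$feature_id,
                   direction = sim$truth$de$direction)
  pairs <- find_cis_pairs(anno[anno$feature_id %in% truth_cis$lncRNA, ],
                          anno[anno$feature_id %in% truth_cis$mRNA, ], de)
  keys <- paste(pairs$lncRNA, pairs$mRNA)
  near <- truth_cis[truth_cis$gap <= 200000, ]
  far <- truth_cis[truth_cis$gap > 200000, ]
  expect_true(all(paste(near$lncRNA, near$mRNA) %in% keys))
  expect_false(any(paste(far$lncRNA, far$mRNA) %in% keys))
  rep <- truth_recovery_report(sim$truth, cis_pairs = pairs)
  expect_identical(rep$recall[rep$stage == "cis"], 1)
})
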