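test_that("miRNA table parses ids and seeds", {
  m <- mirna_table(c("hsa-miR-21-5p", "hsa-miR-4443", "hsa-let-7a-5p"),
                   c("UAGCUUAUCAGACUGAUGUUGA",
                     "UUGGAGGCGCACCC",
                     "UGAGGUAGUAGGUUGUAUAGUU"))
  expect_identical(m$numeric_id, c(21L, 4443L, NA_integer_))
  expect_identical(m$seed[1], "AGCTTAT")   # nt 2-8, U -> T
  expect_error(mirna_table("x", "ACGT"), ">= 8 nt")
})

test_that("id filter keeps miR < 1000 and let-family with a warning", {
  m <- mirna_table(c("hsa-miR-21-5p", "hsa-miR-4443", "hsa-let-7a-5p"),
                   rep("ACGTACGTACGT", 3))
  expect_warning(kept <- filter_mirnas_by_id(m), "let-7a")
  expect_setequal(kept$name, c("hsa-miR-21-5p", "hsa-let-7a-5p"))
})

test_that("seed-site detection classifies planted sites by construction", {
  mir <- mirna_table("hsa-miR-1-3p", "UGGAAUGUAAAGAAGUAUGUAU")
  seed7 <- substr(mir$sequence, 2, 8)                 # GGAATGT
  core_rc <- reverse_complement(substr(mir$sequence, 2, 7))
  full_rc <- reverse_complement(seed7)                # m8 + core
  flank <- "CCCCCCCCCC"
  # 8mer: m8 match plus A opposite nt 1, core starts at offset 11
  tx <- paste0(flank, full_rc, "A", flank)
  s <- find_seed_sites(tx, mir, "t8")
  expect_identical(s$site_type, "8mer")
  expect_identical(s$start, 11L)
  # 7mer-m8: m8 match, non-A at position 1
  s <- find_seed_sites(paste0(flank, full_rc, "G", flank), mir)
  expect_identical(s$site_type, "7mer-m8")
  # 7mer-A1: core only, A anchor
  s <- find_seed_sites(paste0(flank, core_rc, "A", flank), mir)
  expect_identical(s$site_type, "7mer-A1")
  # 6mer: core alone
  s <- find_seed_sites(paste0(flank, core_rc, "G", flank), mir)
  expect_identical(s$site_type, "6mer")
  # no core complement anywhere
  expect_identical(nrow(find_seed_sites(flank, mir)), 0L)
  # N in the window never matches
  tx_n <- paste0(flank, sub("^.", "N", core_rc), "A", flank)
  expect_identical(nrow(find_seed_sites(tx_n, mir)), 0L)
})

test_that("seed-site engine equals the window-enumeration oracle on random data", {
  set.seed(41)
  for (i in 1:15) {
    mseq <- random_dna(22)
    mir <- mirna_table(sprintf("hsa-miR-%d-5p", i), mseq)
    # AT-rich transcripts raise the chance match rate
    tx <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE,
                       prob = c(0.35, 0.15, 0.15, 0.35)), collapse = "")
    got <- find_seed_sites(tx, mir, "tx")
    oracle <- seed_sites_oracle(tx, mir$name, mseq)
    expect_identical(got, oracle)
  }
})

test_that("reported sites re-validate against the seed definition", {
  set.seed(43)
  mir <- mirna_table("hsa-miR-7-5p", random_dna(22))
  tx <- random_dna(5000)
  sites <- find_seed_sites(tx, mir, "tx")
  core_rc <- reverse_complement(substr(mir$sequence, 2, 7))
  full_rc <- reverse_complement(substr(mir$sequence, 2, 8))
  for (i in seq_len(nrow(sites))) {
    at <- sites$start[i] + 1L   # 1-based core start
    expect_identical(substr(tx, at, at + 5L), core_rc)
    if (sites$site_type[i] %in% c("8mer", "7mer-m8"))
      expect_identical(substr(tx, at - 1L, at + 5L), full_rc)
    if (sites$site_type[i] %in% c("8mer", "7mer-A1"))
      expect_identical(substr(tx, at + 6L, at + 6L), "A")
  }
})

cerna_fixture <- function() {
  set.seed(47)
  mirnas <- mirna_table(sprintf("hsa-miR-%d-5p", c(7, 21, 99, 155, 200)),
                        vapply(1:5, function(i) random_dna(22), ""))
  lnc <- setNames(vapply(1:3, function(i) random_dna(300), ""),
                  sprintf("L%d", 1:3))
  mrna <- setNames(vapply(1:10, function(i) random_dna(300), ""),
                   sprintf("M%02d", 1:10))
  # plant sharing: miR-7 on L1+M01 (up/up), miR-21 on L2+M02 (up/down)
  plant <- function(s, mir) {
    site <- paste0(reverse_complement(substr(mir$sequence, 2, 8)), "A")
    paste0(substr(s, 1, 50), site, substr(s, 59, nchar(s)))
  }
  lnc["L1"] <- plant(lnc["L1"], mirnas[1, ])
  mrna["M01"] <- plant(mrna["M01"], mirnas[1, ])
  lnc["L2"] <- plant(lnc["L2"], mirnas[2, ])
  mrna["M02"] <- plant(mrna["M02"], mirnas[2, ])
  de <- data.frame(
    feature_id = c(names(lnc), names(mrna)),
    direction = c("up", "up", "down",
                  "up", "down", rep(c("up", "down"), 4)))
  list(mirnas = mirnas, lnc = lnc, mrna = mrna, de = de)
}

test_that("build_cerna matches brute-force triple enumeration and the direction gate", {
  fx <- cerna_fixture()
  lnc_sites <- scan_seed_sites(fx$lnc, fx$mirnas)
  mrna_sites <- scan_seed_sites(fx$mrna, fx$mirnas)
  triads <- build_cerna(lnc_sites, mrna_sites, fx$de)
  # independent oracle: enumerate all 3 x 5 x 10 = 150 triples
  dirs <- setNames(fx$de$direction, fx$de$feature_id)
  oracle <- NULL
  for (l in names(fx$lnc)) for (mi in seq_len(nrow(fx$mirnas)))
    for (m in names(fx$mrna)) {
      nl <- nrow(seed_sites_oracle(fx$lnc[[l]], "x", fx$mirnas$sequence[mi]))
      nm <- nrow(seed_sites_oracle(fx$mrna[[m]], "x", fx$mirnas$sequence[mi]))
      if (nl >= 1 && nm >= 1 && dirs[[l]] == dirs[[m]])
        oracle <- c(oracle, paste(l, fx$mirnas$name[mi], m))
    }
  expect_setequal(paste(triads$lncRNA, triads$mirna, triads$mRNA), oracle)
  expect_true(paste("L1", fx$mirnas$name[1], "M01") %in%
                paste(triads$lncRNA, triads$mirna, triads$mRNA))
  # discordant planted pair excluded under the gate, included without it
  key21 <- paste("L2", fx$mirnas$name[2], "M02")
  expect_false(key21 %in% paste(triads$lncRNA, triads$mirna, triads$mRNA))
  loose <- build_cerna(lnc_sites, mrna_sites, fx$de,
                       require_same_direction = FALSE)
  expect_true(key21 %in% paste(loose$lncRNA, loose$mirna, loose$mRNA))
  # monotone: the gate and the id filter never add triads
  expect_lte(nrow(triads), nrow(loose))
  few <- suppressWarnings(filter_mirnas_by_id(fx$mirnas, max_id = 100))
  triads_few <- build_cerna(scan_seed_sites(fx$lnc, few),
                            scan_seed_sites(fx$mrna, few), fx$de)
  expect_lte(nrow(triads_few), nrow(triads))
  # unknown transcript is an error
  bad <- lnc_sites; bad$transcript_id[1] <- "ghost"
  expect_error(build_cerna(bad, mrna_sites, fx$de), "ghost")
})

test_that("pathway restriction keeps only mRNAs in allowed sets", {
  triads <- data.frame(lncRNA = c("L1", "L2"), mirna = c("a", "b"),
                       mRNA = c("M01", "M02"))
  sets <- list(cAMP = list(set_id = "cAMP", name = "cAMP signaling",
                           category = "pathway", members = c("G1")),
               other = list(set_id = "other", name = "other",
                            category = "pathway", members = c("G9")))
  sym <- c(M01 = "G1", M02 = "G2")
  kept <- pathway_restrict(triads, sets, "cAMP", symbols = sym)
  expect_identical(kept$mRNA, "M01")
  expect_identical(nrow(pathway_restrict(triads, sets, character(0),
                                         symbols = sym)), 0L)
  expect_error(pathway_restrict(triads, sets, "nope", symbols = sym),
               "unknown gene set")
})
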