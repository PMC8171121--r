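test_that("pooled t-test reproduces the reference cohort p-values", {
  age <- t_test_two_sample(c(84, 83, 93, 93), c(81, 81, 87, 86))
  expect_equal(age$p, 0.207, tolerance = 5e-3)
  dur <- t_test_two_sample(c(140, 155, 190, 80), c(100, 170, 70, 120))
  expect_equal(dur$p, 0.431, tolerance = 5e-3)
})

test_that("t-test agrees with the stats reference and honors conventions", {
  set.seed(5)
  for (i in 1:20) {
    xs <- rnorm(sample(3:9, 1)); ys <- rnorm(sample(3:9, 1), mean = runif(1, -1, 1))
    for (ev in c(TRUE, FALSE)) {
      ours <- t_test_two_sample(xs, ys, equal_variance = ev)
      ref <- t.test(xs, ys, var.equal = ev)
      expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
      expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    }
  }
  same <- t_test_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_identical(c(same$t, same$p), c(0, 1))
  # zero variance conventions
  const <- t_test_two_sample(c(2, 2, 2), c(2, 2, 2))
  expect_identical(c(const$t, const$p), c(0, 1))
  expect_true(const$degenerate)
  sep <- t_test_two_sample(c(2, 2, 2), c(5, 5, 5))
  expect_identical(sep$p, 0)
  expect_true(sep$degenerate)
})

test_that("t-test invariances: group swap and affine rescaling", {
  set.seed(9)
  xs <- rnorm(4, 1); ys <- rnorm(4)
  a <- t_test_two_sample(xs, ys); b <- t_test_two_sample(ys, xs)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  sc <- t_test_two_sample(3 * xs + 7, 3 * ys + 7)
  expect_equal(sc$t, a$t, tolerance = 1e-12)
  expect_equal(sc$p, a$p, tolerance = 1e-12)
})

test_that("linear fold change is symmetric with flipped direction", {
  expect_equal(fold_change_linear(20, 10), list(fold_change = 2, direction = "up"))
  expect_equal(fold_change_linear(10, 20), list(fold_change = 2, direction = "down"))
  expect_equal(fold_change_linear(10, 10), list(fold_change = 1, direction = "down"))
  expect_error(fold_change_linear(0, 10), "positive")
  set.seed(2)
  for (i in 1:10) {
    a <- rexp(1, 1e-3); b <- rexp(1, 1e-3)
    f1 <- fold_change_linear(a, b); f2 <- fold_change_linear(b, a)
    expect_equal(f1$fold_change, f2$fold_change)
    if (a != b) expect_false(f1$direction == f2$direction)
  }
})

test_that("call_de flags obvious signal, never identical groups, and matches the scalar path", {
  set.seed(13)
  n <- 30
  logm <- matrix(rnorm(n * 8, 8, 0.05), n, 8,
                 dimnames = list(sprintf("f%02d", 1:n), sprintf("s%d", 1:8)))
  logm[1, 1:4] <- logm[1, 1:4] + 2         # planted 4-fold up shift
  logm[2, ] <- 6                           # identical groups
  b <- expression_bundle(2^logm)
  de <- call_de(b, design44(b))
  expect_true(de$de[1]); expect_identical(de$direction[1], "up")
  expect_false(de$de[2])
  # dual route: vectorized stats equal the scalar t-test per feature
  for (i in c(1, 5, 12)) {
    ref <- t_test_two_sample(logm[i, 1:4], logm[i, 5:8])
    expect_equal(de$t_statistic[i], ref$t, tolerance = 1e-10)
    expect_equal(de$p_value[i], ref$p, tolerance = 1e-10)
  }
  # fold change on the linear scale
  fc <- fold_change_linear(mean(2^logm[1, 1:4]), mean(2^logm[1, 5:8]))
  expect_equal(de$fold_change[1], fc$fold_change, tolerance = 1e-12)
  expect_equal(de$raw_intensity[1], pmax(de$mean_case, de$mean_control)[1])
})

test_that("validation candidate selection applies strict gates and deterministic tie-breaks", {
  mk <- function(id, fc, p, ri, dirn = "up")
    data.frame(feature_id = id, biotype = NA_character_, fold_change = fc,
               p_value = p, raw_intensity = ri, direction = dirn)
  recs <- do.call(rbind, c(
    lapply(1:30, function(i) mk(sprintf("u%02d", i), 2 + i / 10, 0.01, 1000)),
    list(mk("gate_fc", 2, 0.01, 1000),          # fc not > 2
         mk("gate_int", 3, 0.01, 400),          # intensity not > 500
         mk("gate_p", 3, 0.05, 1000))))         # p not < 0.05
  top <- select_validation_candidates(recs)
  expect_identical(nrow(top), 10L)
  expect_identical(top$feature_id, sprintf("u%02d", 30:21))  # max fold changes
  expect_false(any(c("gate_fc", "gate_int", "gate_p") %in% top$feature_id))
  # ties on fc and p fall back to lexicographic id
  tied <- rbind(mk("b", 3, 0.01, 1000), mk("a", 3, 0.01, 1000))
  got <- suppressWarnings(select_validation_candidates(tied, n_each = 1))
  expect_identical(got$feature_id, "a")
  expect_warning(select_validation_candidates(tied, n_each = 5), "only 2")
})

test_that("concordance rate counts direction-matching qPCR calls", {
  cand <- data.frame(feature_id = sprintf("c%02d", 1:20),
                     direction = rep(c("up", "down"), each = 10))
  qpcr <- data.frame(feature_id = cand$feature_id,
                     qpcr_call = c(rep("up", 7), rep("unchanged", 3),
                                   rep("down", 7), rep("unchanged", 3)))
  expect_equal(concordance_rate(cand, qpcr), 70)
  all_ok <- transform(qpcr, qpcr_call = cand$direction)
  expect_equal(concordance_rate(cand, all_ok), 100)
  none <- transform(qpcr, qpcr_call = "unchanged")
  expect_equal(concordance_rate(cand, none), 0)
  expect_error(concordance_rate(cand, qpcr[-3, ]), "c03")
})

test_that("cluster order reflects correlation distance with UPGMA heights equal to brute force", {
  set.seed(17)
  base <- rnorm(8)
  v <- rbind(f1 = base, f2 = base + rnorm(8, 0, 1e-6),  # near-identical pair
             f3 = rnorm(8), f4 = -base + rnorm(8, 0, 1e-6))
  colnames(v) <- paste0("s", 1:8)
  b <- expression_bundle(v + 100)
  ord <- cluster_order(b, rownames(v))
  pos <- match(c("f1", "f2", "f4"), ord)
  expect_equal(abs(pos[1] - pos[2]), 1)          # identical features adjacent
  expect_gt(abs(pos[1] - pos[3]), 1)             # anti-correlated separated
  # UPGMA merge heights versus an independent brute-force agglomerator
  set.seed(19)
  m <- matrix(rnorm(48), 6, 8,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:8)))
  d <- 1 - cor(t(m))
  upgma_heights <- function(d) {
    d <- as.matrix(d); diag(d) <- Inf
    sizes <- rep(1, nrow(d)); heights <- numeric(0)
    while (nrow(d) > 1) {
      ij <- which(d == min(d), arr.ind = TRUE)[1, ]
      i <- min(ij); j <- max(ij)
      heights <- c(heights, d[i, j])
      merged <- (sizes[i] * d[i, ] + sizes[j] * d[j, ]) / (sizes[i] + sizes[j])
      d[i, ] <- merged; d[, i] <- merged; diag(d) <- Inf
      sizes[i] <- sizes[i] + sizes[j]
      d <- d[-j, -j, drop = FALSE]; sizes <- sizes[-j]
    }
    sort(heights)
  }
  hc <- hclust(as.dist(d), method = "average")
  expect_equal(sort(hc$height), upgma_heights(d), tolerance = 1e-12)
  expect_warning(cluster_order(expression_bundle(rbind(v + 100,
    konst = rep(50, 8))), c("f1", "konst")), "constant")
})
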