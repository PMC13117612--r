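test_that("group detection statistics match a direct per-cell tally", {
  set.seed(11)
  norm <- Matrix::Matrix(matrix(rpois(40 * 30, 0.8), 40, 30,
                                dimnames = list(sprintf("g%02d", 1:40),
                                                sprintf("c%02d", 1:30))),
                         sparse = TRUE)
  labels <- rep(c("A", "B", "C"), each = 10)
  gs <- group_stats(norm, labels, "A", "B")
  for (i in c(1, 7, 40)) {
    xa <- as.numeric(norm[i, labels == "A"])
    xb <- as.numeric(norm[i, labels == "B"])
    expect_equal(gs$pct1[i], mean(xa > 0))
    expect_equal(gs$pct2[i], mean(xb > 0))
    expect_equal(gs$delta_pct[i], mean(xa > 0) - mean(xb > 0))
    expect_equal(gs$mean1[i], mean(xa))
  }
  # worked example: detected in 8/10 vs 3/10 cells
  one <- Matrix::Matrix(matrix(c(rep(1, 8), 0, 0, rep(1, 3), rep(0, 7)),
                               nrow = 1,
                               dimnames = list("g", sprintf("c%d", 1:20))),
                        sparse = TRUE)
  gs1 <- group_stats(one, rep(c("g1", "g2"), each = 10), "g1", "g2")
  expect_equal(gs1$pct1, 0.8)
  expect_equal(gs1$pct2, 0.3)
  expect_equal(gs1$delta_pct, 0.5)
  # identical groups give delta 0
  sym <- group_stats(cbind(norm, norm),
                     rep(c("A", "B"), each = 30), "A", "B")
  expect_true(all(sym$delta_pct == 0))
  expect_error(group_stats(norm, labels, "A", "nope"), "unknown group")
})

test_that("log2 fold change follows the pseudocount formula", {
  expect_equal(log2_fold_change(2, 1), log2((2 + 1e-9) / (1 + 1e-9)))
  expect_lt(abs(log2_fold_change(2, 1) - 1), 1e-8)
  expect_equal(log2_fold_change(5, 5), 0)
  expect_equal(log2_fold_change(0, 1), log2(1e-9 / (1 + 1e-9)))
  expect_lt(log2_fold_change(0, 1), -29.8)
})

test_that("rank-sum p is exact for small tie-free samples", {
  # exhaustive enumeration gives 2/20 for fully separated triples
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(oracle_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # identical samples
  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2, 2)), 1)
  # agreement with the enumeration oracle on all small tie-free inputs
  set.seed(21)
  for (rep in 1:60) {
    nx <- sample(2:6, 1)
    ny <- sample(2:6, 1)
    v <- sample(1000, nx + ny)      # distinct => no ties
    x <- v[seq_len(nx)]
    y <- v[-seq_len(nx)]
    expect_equal(rank_sum_test(x, y), oracle_rank_sum(x, y),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum p-values are near-uniform under the null", {
  set.seed(31)
  p <- replicate(1000, rank_sum_test(rnorm(30), rnorm(30)))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_bh(0.5), 0.5)
  set.seed(41)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- fdr_bh(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("find_markers recovers planted group-specific lncRNAs", {
  # 20 planted markers of group A among 200 null lncRNAs
  set.seed(51)
  n_cells <- 240
  labels <- rep(c("A", "B"), each = n_cells / 2)
  mu <- matrix(1.2, 220, n_cells)
  mu[1:20, labels == "A"] <- 6
  counts <- matrix(rnbinom(length(mu), mu = as.numeric(mu), size = 2),
                   nrow(mu), ncol(mu),
                   dimnames = list(sprintf("lnc%03d", 1:220),
                                   sprintf("c%03d", seq_len(n_cells))))
  norm <- normalize_log(cell_matrix(counts))
  mk <- find_markers(norm, labels, "A", "B")
  flagged <- mk$gene_id[mk$specific]
  expect_gte(sum(sprintf("lnc%03d", 1:20) %in% flagged), 18)
  false_flags <- sum(!flagged %in% sprintf("lnc%03d", 1:20))
  expect_lte(false_flags, ceiling(0.05 * length(flagged)) + 1)
  # antisymmetry under group swap
  mk_rev <- find_markers(norm, labels, "B", "A")
  expect_equal(mk_rev$delta_pct, -mk$delta_pct)
  expect_equal(mk_rev$log2fc, -mk$log2fc, tolerance = 1e-6)
  # zero-variance matrix flags nothing
  flat <- Matrix::Matrix(matrix(1, 5, 20, dimnames = list(
    paste0("g", 1:5), paste0("c", 1:20))), sparse = TRUE)
  mk0 <- find_markers(flat, rep(c("A", "B"), each = 10), "A", "B")
  expect_false(any(mk0$specific))
})

test_that("permutation-null specific-gene rate respects the FDR level", {
  set.seed(61)
  counts <- matrix(rnbinom(60 * 60, mu = 2, size = 2), 60, 60,
                   dimnames = list(paste0("g", 1:60), paste0("c", 1:60)))
  norm <- normalize_log(cell_matrix(counts))
  rates <- replicate(200, {
    labels <- sample(rep(c("A", "B"), each = 30))
    mk <- find_markers(norm, labels, "A", "B", min_delta = 0)
    mean(mk$q < 0.05, na.rm = TRUE)
  })
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lte(mean(rates), 0.05 + 3 * se)
})

test_that("profile clustering is deterministic and recovers archetypes", {
  # noiseless limit: 3 planted archetypes, k = 3, ARI = 1
  groups <- rep(c("G1", "G2", "G3"), each = 12)
  arch <- matrix(0.2, 3, 3)
  diag(arch) <- 4
  truth <- rep(1:3, each = 10)
  prof <- arch[truth, ]
  norm0 <- prof[, rep(1:3, each = 12)]
  dimnames(norm0) <- list(paste0("l", 1:30), paste0("c", 1:36))
  at0 <- cluster_lnc_profiles(norm0, groups, rownames(norm0), k = 3,
                              seed = 9, min_cells = 1)
  expect_equal(ari(at0$atlas$cluster, truth), 1)
  # determinism under the same seed
  at0b <- cluster_lnc_profiles(norm0, groups, rownames(norm0), k = 3,
                               seed = 9, min_cells = 1)
  expect_identical(at0$atlas, at0b$atlas)
  expect_error(cluster_lnc_profiles(norm0[1:2, ], groups,
                                    paste0("l", 1:2), k = 3,
                                    min_cells = 1),
               "fewer")
})

test_that("six-archetype clustering at default noise reaches ARI 0.8", {
  set.seed(71)
  groups6 <- rep(sprintf("G%d", 1:6), each = 25)
  truth <- rep(1:6, each = 20)
  mu <- matrix(1, 120, 150)
  for (i in seq_len(120)) {
    mu[i, groups6 == sprintf("G%d", truth[i])] <- 8
  }
  counts <- matrix(rnbinom(length(mu), mu = as.numeric(mu), size = 2),
                   nrow(mu), ncol(mu),
                   dimnames = list(sprintf("l%03d", 1:120),
                                   sprintf("c%03d", 1:150)))
  norm <- normalize_log(cell_matrix(counts))
  at <- cluster_lnc_profiles(norm, groups6, rownames(norm), k = 6,
                             seed = 3)
  kept <- match(at$atlas$gene_id, rownames(norm))
  expect_gte(ari(at$atlas$cluster, truth[kept]), 0.8)
})
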