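test_that("MTX triplet directories round-trip, plain and gzipped", {
  m <- toy_cell_matrix()
  for (gz in c(FALSE, TRUE)) {
    dir <- withr::local_tempdir()
    write_mtx_triplet(m, dir, gzip = gz)
    back <- read_mtx_triplet(dir)
    expect_equal(as.matrix(back$counts), as.matrix(m$counts))
    expect_equal(back$gene_meta$gene_name, m$gene_meta$gene_name)
    expect_equal(back$cell_meta$cell_id, m$cell_meta$cell_id)
  }
})

test_that("shape/label mismatches are reported with the offending file", {
  m <- toy_cell_matrix()
  dir <- withr::local_tempdir()
  write_mtx_triplet(m, dir)
  writeLines(c("c1", "c2", "c3"), file.path(dir, "barcodes.tsv"))
  expect_error(read_mtx_triplet(dir), "barcodes")
  write_mtx_triplet(m, dir)
  writeLines("onlyone\tname", file.path(dir, "features.tsv"))
  expect_error(read_mtx_triplet(dir), "features")
  unlink(file.path(dir, "matrix.mtx"))
  expect_error(read_mtx_triplet(dir), "matrix.mtx")
})

test_that("per-cell QC statistics follow the worked examples", {
  m <- toy_cell_matrix()   # c1: geneA 5, MT 5; c2: geneB 3, MT 1
  qc <- compute_cell_qc(m)
  expect_equal(qc$total_umi, c(10, 4))
  expect_equal(qc$n_genes, c(2L, 2L))
  expect_equal(qc$mito_frac, c(0.5, 0.25))

  # all-zero cell: documented 0/0 = 0 convention
  z <- matrix(0, 2, 1, dimnames = list(c("a", "MT-1"), "c"))
  qz <- compute_cell_qc(cell_matrix(z, gene_meta = tibble::tibble(
    gene_id = c("a", "MT-1"), gene_name = c("a", "MT-1"))))
  expect_equal(unlist(qz[1, c("total_umi", "n_genes", "mito_frac")]),
               c(total_umi = 0, n_genes = 0, mito_frac = 0))
})

test_that("QC boundary semantics match the stated inequalities exactly", {
  # one gene per detection slot; cells engineered to sit exactly on each
  # boundary. 6,000 genes so gene-count bounds are reachable.
  n_genes <- 6000
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  gene_names <- gene_ids
  gene_names[n_genes] <- "MT-X"
  build_cell <- function(umi, genes, mito_frac, eps = 0) {
    v <- numeric(n_genes)
    mito <- round(umi * mito_frac + eps)
    rest <- umi - mito
    base <- rest %/% (genes - 1)
    extra <- rest %% (genes - 1)
    v[seq_len(genes - 1)] <- base
    if (extra > 0) v[seq_len(extra)] <- v[seq_len(extra)] + 1
    v[n_genes] <- mito
    v
  }
  cells <- cbind(
    pass = build_cell(3500, 1500, 0.04),
    umi_low = build_cell(3499, 1500, 0.04),
    genes_high = build_cell(6000, 5001, 0.04),
    mito_at = build_cell(3600, 1500, 0.05),
    doublet_at = build_cell(3600, 1500, 0.04)
  )
  rownames(cells) <- gene_ids
  meta <- tibble::tibble(
    cell_id = colnames(cells),
    doublet_score = c(0.49, 0.1, 0.1, 0.1, 0.50)
  )
  m <- cell_matrix(cells, cell_meta = meta, gene_meta = tibble::tibble(
    gene_id = gene_ids, gene_name = gene_names))
  qc <- compute_cell_qc(m)
  expect_equal(qc$total_umi[1], 3500)
  expect_equal(qc$n_genes[1], 1500L)
  expect_lt(qc$mito_frac[1], 0.05)
  res <- apply_qc(m, qc_thresholds())
  keep <- stats::setNames(res$cell_qc$keep, res$cell_qc$cell_id)
  expect_true(keep[["pass"]])
  expect_false(keep[["umi_low"]])
  expect_false(keep[["genes_high"]])
  expect_false(keep[["mito_at"]])       # mito strictly < 5%
  expect_false(keep[["doublet_at"]])    # doublet strictly < 0.5
  fail <- stats::setNames(res$cell_qc$fail_rule, res$cell_qc$cell_id)
  expect_equal(unname(fail[c("umi_low", "genes_high", "mito_at",
                             "doublet_at")]),
               c("umi_min", "genes_max", "mito", "doublet"))
})

test_that("apply_qc is idempotent and monotone in thresholds", {
  cfg <- sim_config(seed = 31, n_pairs = 20, n_extra_pcgs = 300,
                    n_extra_lncs = 180, n_cells_per_group = 30,
                    n_doublets = 5,
                    qc_fail_plan = c(umi_low = 3, mito = 3))
  sim <- simulate_counts(cfg, simulate_annotation(cfg))
  res1 <- apply_qc(sim$matrix, cfg$qc)
  res2 <- apply_qc(res1$matrix, cfg$qc)
  expect_equal(ncol(res2$matrix$counts), ncol(res1$matrix$counts))
  expect_equal(sum(res2$removed$n_removed), 0)
  # tightening any threshold never increases the retained count
  tighter <- list(
    qc_thresholds(umi_min = cfg$qc$umi_min + 2000,
                  genes_min = cfg$qc$genes_min,
                  genes_max = cfg$qc$genes_max),
    qc_thresholds(umi_max = 20000, genes_min = cfg$qc$genes_min,
                  genes_max = cfg$qc$genes_max),
    qc_thresholds(genes_min = cfg$qc$genes_min + 200,
                  genes_max = cfg$qc$genes_max),
    qc_thresholds(genes_min = cfg$qc$genes_min,
                  genes_max = cfg$qc$genes_max, mito_max_frac = 0.01),
    qc_thresholds(genes_min = cfg$qc$genes_min,
                  genes_max = cfg$qc$genes_max, doublet_threshold = 0.2)
  )
  n_base <- ncol(res1$matrix$counts)
  for (t in tighter) {
    expect_lte(ncol(apply_qc(sim$matrix, t)$matrix$counts), n_base)
  }
})

test_that("normalize_log follows the CP10k-log1p formula and preserves zeros", {
  counts <- matrix(c(10, 0, 9990,
                     2, 2, 0), nrow = 3,
                   dimnames = list(c("a", "b", "c"), c("c1", "c2")))
  norm <- normalize_log(cell_matrix(counts))
  expect_equal(norm["a", "c1"], log(11))       # 10 * 1e4/1e4 = 10
  expect_equal(norm["b", "c1"], 0)
  expect_equal(norm["c", "c2"], 0)
  expect_equal(norm["a", "c2"], log1p(2 * 1e4 / 4))
  expect_equal(as.matrix(norm) == 0, counts == 0)
  # strict monotonicity within a cell
  expect_true(norm["c", "c1"] > norm["a", "c1"])
  # column permutation permutes output identically
  norm_rev <- normalize_log(cell_matrix(counts[, 2:1]))
  expect_equal(as.matrix(norm_rev), as.matrix(norm)[, 2:1])
  # all-zero cell: zero column with a warning
  cz <- matrix(c(1, 0), 1, 2, dimnames = list("a", c("c1", "c2")))
  expect_warning(nz <- normalize_log(cell_matrix(cz)), "all-zero")
  expect_equal(as.numeric(nz[1, ]), c(log1p(1e4), 0))
})

test_that("biotype accounting matches planted shares and sums to one", {
  ann <- make_annotation(
    make_gene("lncA", "chr1", "+", 1, 100, biotype = "lncRNA"),
    make_gene("pcgA", "chr1", "+", 200, 300),
    make_gene("pcgB", "chr1", "+", 400, 500)
  )
  counts <- matrix(c(3, 50, 47), nrow = 3, ncol = 1,
                   dimnames = list(c("lncA", "pcgA", "pcgB"), "c1"))
  bf <- biotype_fraction(cell_matrix(counts), ann)
  expect_equal(sum(bf$umi_fraction), 1)
  expect_equal(bf$umi_fraction[bf$biotype == "lncRNA"], 0.03)
  expect_equal(bf$umi_fraction[bf$biotype == "other"], 0)
  # single-biotype matrix
  bf2 <- biotype_fraction(cell_matrix(counts[2:3, , drop = FALSE]), ann)
  expect_equal(bf2$umi_fraction[bf2$biotype == "protein_coding"], 1)
  # unresolvable ids count as "other"
  counts3 <- counts
  rownames(counts3)[1] <- "mystery"
  bf3 <- biotype_fraction(cell_matrix(counts3), ann)
  expect_equal(bf3$umi_fraction[bf3$biotype == "other"], 0.03)
})

test_that("generator lncRNA UMI share lands near the planted 3.47%", {
  cfg <- sim_config(seed = 17, n_pairs = 40, n_extra_pcgs = 400,
                    n_extra_lncs = 250, n_cells_per_group = 40,
                    n_doublets = 0, qc_fail_plan = c(umi_low = 0))
  sim <- simulate_counts(cfg, simulate_annotation(cfg))
  ann <- simulate_annotation(cfg)$annotation
  bf <- biotype_fraction(sim$matrix, ann)
  share <- bf$umi_fraction[bf$biotype == "lncRNA"]
  expect_gt(share, 0.033)
  expect_lt(share, 0.037)
})
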