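test_that("proximal pairing respects the 5-kb span gap rule", {
  ann <- make_annotation(
    make_gene("L1", "chr1", "-", 9000, 9800, biotype = "lncRNA"),
    make_gene("L2", "chr1", "-", 1000, 2000, biotype = "lncRNA"),
    make_gene("P1", "chr1", "+", 10000, 20000)
  )
  pt <- find_proximal_pairs(ann, window_bp = 5000)
  expect_equal(nrow(pt), 1)              # L2 is 8,000 bp away: excluded
  expect_equal(pt$lnc_id, "L1")
  expect_equal(pt$gap_bp, 200L)
  expect_error(find_proximal_pairs(ann, window_bp = 0), "positive")
})

test_that("the six worked configuration examples classify as forced", {
  pcg <- example_pcg()
  expect_equal(classify_configuration(
    make_gene("L", "chr1", "-", 12000, 12400, "lncRNA"), pcg), "XI")
  expect_equal(classify_configuration(
    make_gene("L", "chr1", "-", 9000, 9800, "lncRNA"), pcg), "XH")
  expect_equal(classify_configuration(
    make_gene("L", "chr1", "-", 20500, 21200, "lncRNA"), pcg), "XT")
  expect_equal(classify_configuration(
    make_gene("L", "chr1", "+", 8000, 9000, "lncRNA"), pcg), "SU")
  expect_equal(classify_configuration(
    make_gene("L", "chr1", "+", 21000, 21800, "lncRNA"), pcg), "SD")
  expect_equal(classify_configuration(
    make_gene("L", "chr1", "-", 10200, 11000, "lncRNA",
              exons = rbind(c(10200, 10400), c(10800, 11000))), pcg),
    "XO")
  expect_error(classify_configuration(
    make_gene("L", "chr2", "-", 9000, 9800, "lncRNA"), pcg),
    "different chromosomes")
})

test_that("classification agrees with the position-set oracle on random layouts", {
  set.seed(101)
  n_checked <- 0
  while (n_checked < 2000) {
    lay <- random_layout()
    if (is.null(lay)) next
    expect_equal(classify_configuration(lay$lnc, lay$pcg),
                 oracle_classify(lay$lnc, lay$pcg))
    n_checked <- n_checked + 1
  }
})

test_that("labels are invariant under strand-flip plus coordinate mirror", {
  set.seed(202)
  n_checked <- 0
  while (n_checked < 500) {
    lay <- random_layout()
    if (is.null(lay)) next
    lab <- classify_configuration(lay$lnc, lay$pcg)
    lab_m <- classify_configuration(mirror_gene(lay$lnc),
                                    mirror_gene(lay$pcg))
    expect_equal(lab_m, lab)
    n_checked <- n_checked + 1
  }
})

test_that("the six labels partition pairs by strand relation", {
  set.seed(303)
  n_checked <- 0
  while (n_checked < 500) {
    lay <- random_layout()
    if (is.null(lay)) next
    lab <- classify_configuration(lay$lnc, lay$pcg)
    expect_length(lab, 1)
    if (lay$lnc$strand == lay$pcg$strand) {
      expect_true(lab %in% c("SU", "SD"))
    } else {
      expect_true(lab %in% c("XO", "XI", "XH", "XT"))
    }
    n_checked <- n_checked + 1
  }
})

test_that("pair discovery equals the all-pairs brute-force oracle", {
  set.seed(404)
  genes <- list()
  for (i in 1:200) {
    chrom <- sample(paste0("chr", 1:3), 1)
    start <- sample(1:200000, 1)
    len <- sample(200:8000, 1)
    bt <- sample(c("lncRNA", "protein_coding"), 1)
    genes[[i]] <- make_gene(sprintf("G%03d", i), chrom,
                            sample(c("+", "-"), 1), start,
                            start + len - 1L, biotype = bt)
  }
  ann <- make_annotation(genes)
  got <- find_proximal_pairs(ann, window_bp = 5000)
  want <- oracle_pairs(ann, window_bp = 5000)
  key <- function(a, b) paste(a, b)
  expect_setequal(key(got$lnc_id, got$pcg_id),
                  key(want$lnc_id, want$pcg_id))
  merged <- dplyr::inner_join(tibble::as_tibble(got), want,
                              by = c("lnc_id", "pcg_id"))
  expect_equal(merged$gap_bp.x, merged$gap_bp.y)
})

test_that("fixed-window mode pairs genes whose TSSs share a bin", {
  ann <- make_annotation(
    # TSS 4,900 (minus strand: TSS = end) and TSS 4,950: same 5-kb bin
    make_gene("L1", "chr1", "-", 4000, 4900, biotype = "lncRNA"),
    make_gene("P1", "chr1", "+", 4950, 30000),
    # TSS 5,100: next bin, despite tiny gap to P1
    make_gene("L2", "chr1", "-", 5050, 5100, biotype = "lncRNA")
  )
  pt <- find_proximal_pairs(ann, window_bp = 5000, mode = "fixed-window")
  expect_equal(nrow(pt), 1)
  expect_equal(pt$lnc_id, "L1")
})

test_that("configuration frequencies cover all six labels and sum to one", {
  ann <- make_annotation(
    make_gene("L1", "chr1", "-", 900, 950, biotype = "lncRNA"),
    make_gene("L2", "chr1", "-", 3000, 3050, biotype = "lncRNA"),
    make_gene("P1", "chr1", "+", 1000, 2000)
  )
  pt <- find_proximal_pairs(ann)
  fr <- configuration_frequencies(pt)
  expect_equal(sum(fr$fraction), 1)
  expect_equal(nrow(fr), 6)
  expect_equal(fr$fraction[fr$configuration == "XH"], 0.5)
  expect_equal(fr$fraction[fr$configuration == "XT"], 0.5)
  # restriction to expressed genes
  fr2 <- configuration_frequencies(pt, expressed = c("L1", "P1"))
  expect_equal(fr2$fraction[fr2$configuration == "XH"], 1)
  expect_error(configuration_frequencies(pt, expressed = "L1"),
               "no pairs")
  # single-pair table
  one <- pt[1, ]
  fr3 <- configuration_frequencies(one)
  expect_equal(max(fr3$fraction), 1)
})

test_that("frequencies of 4 pairs labelled XH,XH,SU,SD match the worked example", {
  pt <- tibble::tibble(
    lnc_id = paste0("L", 1:4), pcg_id = paste0("P", 1:4),
    configuration = factor(c("XH", "XH", "SU", "SD"),
                           levels = CONFIGURATIONS)
  )
  fr <- configuration_frequencies(pt)
  got <- stats::setNames(fr$fraction, as.character(fr$configuration))
  expect_equal(got, c(XH = 0.5, XT = 0, XI = 0, XO = 0,
                      SU = 0.25, SD = 0.25))
})

test_that("nearest_pcg minimises gap with documented tie-breaks", {
  lnc <- make_gene("L", "chr1", "+", 5000, 5500, biotype = "lncRNA")
  ann <- make_annotation(
    lnc,
    make_gene("A", "chr1", "+", 5600, 6000),    # gap 100
    make_gene("B", "chr1", "+", 5800, 6100)     # gap 300
  )
  expect_equal(nearest_pcg(lnc, ann), "A")
  # tie on gap: 5'-most start wins
  ann2 <- make_annotation(
    lnc,
    make_gene("X", "chr1", "+", 1000, 4900),    # gap 100
    make_gene("Y", "chr1", "+", 5600, 7000)     # gap 100
  )
  expect_equal(nearest_pcg(lnc, ann2), "X")
  # no PCG within window
  expect_identical(nearest_pcg(lnc, ann, window_bp = 50), NA_character_)
})

test_that("nearest_pcg equals the brute-force argmin on random layouts", {
  set.seed(505)
  for (rep in 1:50) {
    genes <- lapply(1:20, function(i) {
      start <- sample(1:50000, 1)
      make_gene(sprintf("P%02d", i), "chr1", sample(c("+", "-"), 1),
                start, start + sample(100:2000, 1))
    })
    ann <- make_annotation(genes)
    lnc <- make_gene("L", "chr1", "+", 20000, 20500, biotype = "lncRNA")
    gaps <- vapply(genes, function(g) {
      max(0, max(g$start, lnc$start) - min(g$end, lnc$end))
    }, numeric(1))
    starts <- vapply(genes, function(g) g$start, integer(1))
    ids <- vapply(genes, function(g) g$gene_id, character(1))
    ord <- order(gaps, starts, ids)
    expect_equal(nearest_pcg(lnc, ann), ids[ord[1]])
  }
})
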