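# Small deterministic fixtures used across test files.

# one-row gene tibble in the annotation layout
make_gene <- function(id, chrom, strand, start, end,
                      biotype = "protein_coding", exons = NULL) {
  if (is.null(exons)) {
    exons <- matrix(c(start, end), ncol = 2,
                    dimnames = list(NULL, c("start", "end")))
  } else {
    exons <- matrix(as.integer(t(exons)), ncol = 2, byrow = TRUE,
                    dimnames = list(NULL, c("start", "end")))
  }
  tibble::tibble(gene_id = id, gene_name = id, chrom = chrom,
                 strand = strand, start = as.integer(start),
                 end = as.integer(end), biotype = biotype,
                 exons = list(exons))
}

make_annotation <- function(...) {
  lncpair:::new_annotation(dplyr::bind_rows(...))
}

# the worked two-gene locus used in the classification examples:
# pcg on + strand, 10,000-20,000, exons at both ends
example_pcg <- function() {
  make_gene("PCG", "chr1", "+", 10000, 20000,
            exons = rbind(c(10000, 10500), c(19500, 20000)))
}

write_toy_gtf <- function(path, quoted = TRUE) {
  attr1 <- if (quoted) {
    'gene_id "G1"; gene_name "GENE1"; gene_type "protein_coding";'
  } else {
    "gene_id G1; gene_name GENE1; gene_type protein_coding;"
  }
  attr2 <- if (quoted) {
    'gene_id "G2"; gene_name "LNC1"; gene_type "lncRNA";'
  } else {
    "gene_id G2; gene_name LNC1; gene_type lncRNA;"
  }
  lines <- c(
    "## toy annotation",
    paste("chr1", "src", "gene", 100, 1000, ".", "+", ".", attr1,
          sep = "\t"),
    paste("chr1", "src", "exon", 100, 300, ".", "+", ".", attr1,
          sep = "\t"),
    paste("chr1", "src", "exon", 700, 1000, ".", "+", ".", attr1,
          sep = "\t"),
    paste("chr1", "src", "gene", 2000, 2500, ".", "-", ".", attr2,
          sep = "\t"),
    paste("chr1", "src", "exon", 2000, 2500, ".", "-", ".", attr2,
          sep = "\t")
  )
  writeLines(lines, path)
  path
}

# tiny deterministic count container: 3 genes x 2 cells
toy_cell_matrix <- function() {
  m <- matrix(c(5, 0, 5,
                0, 3, 1), nrow = 3,
              dimnames = list(c("geneA", "geneB", "MTG1"),
                              c("c1", "c2")))
  gm <- tibble::tibble(gene_id = rownames(m),
                       gene_name = c("geneA", "geneB", "MT-CO1"))
  cell_matrix(m, gene_meta = gm)
}

# adjusted Rand index for clustering agreement
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
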