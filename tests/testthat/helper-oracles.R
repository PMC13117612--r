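# Independent oracles. These re-derive expected results from first
# principles (base-pair position sets, exhaustive enumeration, direct
# loops) and are kept deliberately naive.

# strand-aware ends from the definition
oracle_tss <- function(g) if (g$strand == "+") g$start else g$end
oracle_tes <- function(g) if (g$strand == "+") g$end else g$start

# exhaustive case analysis of a lncRNA-PCG configuration using
# base-pair position sets; genes must be short enough to enumerate
oracle_classify <- function(lnc, pcg) {
  stopifnot(lnc$chrom == pcg$chrom)
  span_pos <- function(g) seq.int(g$start, g$end)
  exon_pos <- function(g) {
    ex <- g$exons[[1]]
    unique(unlist(lapply(seq_len(nrow(ex)),
                         function(i) seq.int(ex[i, 1], ex[i, 2]))))
  }
  if (lnc$strand != pcg$strand) {
    if (length(intersect(exon_pos(lnc), exon_pos(pcg))) >= 1) return("XO")
    if (all(span_pos(lnc) %in% span_pos(pcg))) return("XI")
    d_head <- abs(oracle_tss(lnc) - oracle_tss(pcg))
    d_tail <- abs(oracle_tes(lnc) - oracle_tes(pcg))
    return(if (d_head <= d_tail) "XH" else "XT")
  }
  # sense: canonicalise by mirroring so the shared strand reads +, then
  # upstream is simply "smaller coordinate"
  if (lnc$strand == "+") {
    if (oracle_tss(lnc) < oracle_tss(pcg)) "SU" else "SD"
  } else {
    if (-oracle_tss(lnc) < -oracle_tss(pcg)) "SU" else "SD"
  }
}

# brute-force all-pairs proximal pair discovery
oracle_pairs <- function(ann, window_bp = 5000) {
  lnc <- ann[ann$biotype == "lncRNA", ]
  pcg <- ann[ann$biotype == "protein_coding", ]
  out <- list()
  for (i in seq_len(nrow(lnc))) {
    for (j in seq_len(nrow(pcg))) {
      if (lnc$chrom[i] != pcg$chrom[j]) next
      gap <- max(0, max(lnc$start[i], pcg$start[j]) -
                   min(lnc$end[i], pcg$end[j]))
      if (gap <= window_bp) {
        out[[length(out) + 1]] <- c(lnc$gene_id[i], pcg$gene_id[j], gap)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(lnc_id = character(), pcg_id = character(),
                          gap_bp = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(lnc_id = m[, 1], pcg_id = m[, 2],
                 gap_bp = as.integer(m[, 3]))
}

# exact two-sided rank-sum p by enumerating all labelings
oracle_rank_sum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(m)])
  combs <- utils::combn(n, m)
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- m * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# BH step-up from the definition: q_i = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# random two-gene layout on one chromosome; short genes so the position
# set oracle stays cheap
random_layout <- function() {
  rand_gene <- function(id, biotype) {
    start <- sample(1000:6000, 1)
    len <- sample(40:800, 1)
    end <- start + len - 1L
    n_ex <- sample(1:3, 1)
    cuts <- sort(sample(seq.int(start, end), 2 * n_ex))
    ex <- matrix(cuts, ncol = 2, byrow = TRUE)
    make_gene(id, "chr1", sample(c("+", "-"), 1), start, end,
              biotype = biotype, exons = ex)
  }
  lnc <- rand_gene("L", "lncRNA")
  pcg <- rand_gene("P", "protein_coding")
  gap <- max(0, max(lnc$start, pcg$start) - min(lnc$end, pcg$end))
  if (gap > 5000) return(NULL)
  list(lnc = lnc, pcg = pcg)
}

# mirror a gene through coordinate C and flip its strand
mirror_gene <- function(g, c0 = 10000L) {
  ex <- g$exons[[1]]
  mex <- cbind(c0 - ex[, 2], c0 - ex[, 1])
  mex <- mex[order(mex[, 1]), , drop = FALSE]
  make_gene(g$gene_id, g$chrom, if (g$strand == "+") "-" else "+",
            c0 - g$end, c0 - g$start, biotype = g$biotype, exons = mex)
}
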