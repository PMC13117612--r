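#' Per-gene detection and mean statistics for a two-group contrast
#'
#' `pct1`/`pct2` are fractions of cells with a detected (non-zero) value;
#' means are taken on the supplied normalised values.
#'
#' @param norm genes x cells normalised matrix (zero pattern equals the
#'   raw-count zero pattern, so detection can be read off it).
#' @param labels Character vector of group labels, one per column.
#' @param group1,group2 Labels to contrast.
#' @return Tibble with `gene_id`, `pct1`, `pct2`, `delta_pct`, `mean1`,
#'   `mean2`.
#' @export
group_stats <- function(norm, labels, group1, group2) {
  if (length(labels) != ncol(norm)) {
    stop("labels length must equal the number of cells")
  }
  for (g in c(group1, group2)) {
    if (!g %in% labels) stop("unknown group label: ", g)
  }
  i1 <- labels == group1
  i2 <- labels == group2
  m1 <- norm[, i1, drop = FALSE]
  m2 <- norm[, i2, drop = FALSE]
  tibble::tibble(
    gene_id = rownames(norm),
    pct1 = as.numeric(Matrix::rowSums(m1 > 0)) / sum(i1),
    pct2 = as.numeric(Matrix::rowSums(m2 > 0)) / sum(i2),
    mean1 = as.numeric(Matrix::rowMeans(m1)),
    mean2 = as.numeric(Matrix::rowMeans(m2))
  ) |>
    dplyr::mutate(delta_pct = .data$pct1 - .data$pct2,
                  .after = "pct2")
}

#' Log2 fold change of two means with a pseudocount
#'
#' `log2((mean1 + eps) / (mean2 + eps))`.
#'
#' @param mean1,mean2 Non-negative means (vectorised).
#' @param eps Pseudocount guarding zero means (default 1e-9).
#' @return Numeric vector.
#' @export
log2_fold_change <- function(mean1, mean2, eps = 1e-9) {
  log2((mean1 + eps) / (mean2 + eps))
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when the pooled sample size is at most 12 and the
#' values are tie-free; otherwise the normal approximation with tie and
#' continuity corrections. Two identical constant samples give p = 1.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  pooled <- c(x, y)
  if (stats::var(pooled) == 0 || length(unique(pooled)) == 1) return(1)
  has_ties <- anyDuplicated(pooled) > 0
  use_exact <- (length(x) + length(y) <= 12) && !has_ties
  res <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = use_exact, correct = TRUE
  ))
  unname(res$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate control; `NA` p-values are passed
#' through.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
fdr_bh <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Score group-specific genes (volcano-style marker table)
#'
#' Wilcoxon rank-sum test on normalised values per gene, with detection
#' percentages, delta percentage, log2 fold change and BH q-values. A
#' gene is flagged `specific` when `q < alpha`, `delta_pct >= min_delta`
#' and `log2fc > 0`. Fold changes are taken on the linear normalised
#' scale (`expm1` of the log-normalised input), the convention of the
#' standard single-cell marker callers; the rank-sum test runs on the
#' log-normalised values.
#'
#' @inheritParams group_stats
#' @param min_delta Minimum `pct1 - pct2` for the specific flag.
#' @param alpha FDR level for the specific flag.
#' @param eps Pseudocount for the fold change.
#' @return A tibble of class `marker_table`: `gene_id`, `group1`,
#'   `group2`, `pct1`, `pct2`, `delta_pct`, `log2fc`, `p`, `q`,
#'   `specific`.
#' @export
find_markers <- function(norm, labels, group1, group2,
                         min_delta = 0.1, alpha = 0.05, eps = 1e-9) {
  gs <- group_stats(norm, labels, group1, group2)
  i1 <- which(labels == group1)
  i2 <- which(labels == group2)
  dense <- as.matrix(norm)
  p <- vapply(seq_len(nrow(dense)), function(i) {
    rank_sum_test(dense[i, i1], dense[i, i2])
  }, numeric(1))
  lin <- expm1(dense)
  lin_mean1 <- rowMeans(lin[, i1, drop = FALSE])
  lin_mean2 <- rowMeans(lin[, i2, drop = FALSE])
  out <- gs |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      group1 = group1,
      group2 = group2,
      pct1 = .data$pct1,
      pct2 = .data$pct2,
      delta_pct = .data$delta_pct,
      log2fc = log2_fold_change(lin_mean1, lin_mean2, eps),
      mean1 = lin_mean1,
      mean2 = lin_mean2,
      p = p
    ) |>
    dplyr::mutate(
      q = fdr_bh(.data$p),
      specific = .data$q < alpha & .data$delta_pct >= min_delta &
        .data$log2fc > 0
    )
  structure(out, class = c("marker_table", class(tibble::tibble())))
}

#' Cluster lncRNA group-mean profiles into an expression atlas
#'
#' Group-mean profiles of detected lncRNAs are z-scored per gene and
#' partitioned with seeded k-means (best of `nstart` restarts, capped
#' iterations), the documented stand-in for the six-cluster atlas.
#'
#' @param norm genes x cells normalised matrix.
#' @param labels Per-cell group labels.
#' @param lnc_ids Gene ids to cluster (the lncRNAs).
#' @param k Number of clusters (default 6).
#' @param seed RNG seed making the partition reproducible.
#' @param min_cells Minimum number of cells detecting a gene for it to
#'   enter the atlas (default 10).
#' @param nstart,iter_max k-means restarts and iteration cap.
#' @return A list of class `lnc_atlas`: `atlas` (tibble `gene_id`,
#'   `cluster`), `centers` (k x groups matrix of z-scored profiles), `k`,
#'   `seed`.
#' @export
cluster_lnc_profiles <- function(norm, labels, lnc_ids, k = 6, seed = 1,
                                 min_cells = 10, nstart = 10,
                                 iter_max = 100) {
  rows <- intersect(lnc_ids, rownames(norm))
  sub <- norm[rows, , drop = FALSE]
  detected <- Matrix::rowSums(sub > 0) >= min_cells
  sub <- sub[detected, , drop = FALSE]
  groups <- sort(unique(labels))
  prof <- vapply(groups, function(g) {
    as.numeric(Matrix::rowMeans(sub[, labels == g, drop = FALSE]))
  }, numeric(nrow(sub)))
  rownames(prof) <- rownames(sub)
  sds <- apply(prof, 1, stats::sd)
  prof <- prof[sds > 0, , drop = FALSE]
  if (nrow(prof) < k) {
    stop("fewer informative lncRNA profiles (", nrow(prof),
         ") than clusters (", k, ")")
  }
  z <- t(scale(t(prof)))
  km <- withr::with_seed(seed, stats::kmeans(
    z, centers = k, nstart = nstart, iter.max = iter_max
  ))
  structure(list(
    atlas = tibble::tibble(gene_id = rownames(z),
                           cluster = as.integer(km$cluster)),
    centers = km$centers,
    k = k,
    seed = seed
  ), class = "lnc_atlas")
}

#' @export
print.lnc_atlas <- function(x, ...) {
  cat("<lnc_atlas> ", nrow(x$atlas), " lncRNAs in ", x$k, " clusters\n",
      sep = "")
  invisible(x)
}
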