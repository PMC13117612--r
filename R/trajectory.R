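#' Select trajectory ordering genes
#'
#' A gene orders a trajectory when its endpoint contrast shows
#' `|log2fc| >= log2fc_min`, adjusted p below `q_max`, and its mean
#' expression is within the top `top_expr_frac` of tested genes
#' (at or above the `1 - top_expr_frac` quantile). The absolute fold
#' change is used because a gene strongly up at either endpoint is
#' informative for ordering.
#'
#' @param markers A [find_markers()] table for the trajectory's endpoint
#'   contrast (columns `gene_id`, `log2fc`, `q`).
#' @param expr_means Named numeric vector of mean normalised expression
#'   over the trajectory's cells, covering the tested genes.
#' @param log2fc_min Fold-change threshold (default 2).
#' @param q_max Adjusted-p threshold (default 0.05).
#' @param top_expr_frac Expression-rank fraction kept (default 0.2).
#' @return Character vector of selected gene ids.
#' @export
select_ordering_genes <- function(markers, expr_means, log2fc_min = 2,
                                  q_max = 0.05, top_expr_frac = 0.2) {
  if (!nrow(markers)) stop("empty marker table")
  mu <- expr_means[markers$gene_id]
  if (anyNA(mu)) stop("expr_means must cover every tested gene")
  cutoff <- stats::quantile(mu, 1 - top_expr_frac, names = FALSE)
  sel <- abs(markers$log2fc) >= log2fc_min &
    !is.na(markers$q) & markers$q < q_max &
    mu >= cutoff
  markers$gene_id[sel]
}

#' Equal-occupancy pseudotime binning
#'
#' Cells are ranked by pseudotime (ties broken by stable input order)
#' and split into `n_bins` bins of near-equal occupancy; per-bin means
#' of the expression and of pseudotime (the bin centre) are returned.
#'
#' @param expr Per-cell expression values.
#' @param pseudotime Per-cell pseudotime, same length.
#' @param n_bins Number of bins (default 20); requires at least `n_bins`
#'   cells.
#' @return Tibble with `bin`, `center`, `mean`.
#' @export
bin_smooth <- function(expr, pseudotime, n_bins = 20) {
  stopifnot(length(expr) == length(pseudotime))
  n <- length(expr)
  if (n < n_bins) stop("need at least n_bins (", n_bins, ") cells, got ", n)
  ord <- order(pseudotime)          # stable in R
  idx <- ceiling(seq_len(n) * n_bins / n)
  centers <- as.numeric(tapply(pseudotime[ord], idx, mean))
  means <- as.numeric(tapply(expr[ord], idx, mean))
  tibble::tibble(bin = seq_len(n_bins), center = centers, mean = means)
}

#' Pseudotime co-dynamics of a gene pair
#'
#' Pearson test on the two binned pseudotime profiles (n = `n_bins`).
#'
#' @param lnc_expr,pcg_expr Per-cell expression of the two genes.
#' @inheritParams bin_smooth
#' @return A [pearson_cor_test()] result list (`r`, `p`, `n`, `defined`);
#'   constant profiles are flagged undefined.
#' @export
trajectory_correlation <- function(lnc_expr, pcg_expr, pseudotime,
                                   n_bins = 20) {
  a <- bin_smooth(lnc_expr, pseudotime, n_bins)
  b <- bin_smooth(pcg_expr, pseudotime, n_bins)
  pearson_cor_test(a$mean, b$mean)
}

#' Define a lineage trajectory
#'
#' @param name Trajectory name (e.g. `"CTB_to_STB"`).
#' @param groups Ordered group labels included in the trajectory; the
#'   first and last are the endpoint contrast.
#' @return A list of class `trajectory_def`.
#' @export
trajectory_def <- function(name, groups) {
  stopifnot(length(groups) >= 2)
  structure(list(name = name, groups = groups), class = "trajectory_def")
}

#' Call high-confidence cis-regulatory pairs along trajectories
#'
#' For each trajectory, pairs whose two members are both ordering genes
#' (when `require_both_dynamic`) are scored with
#' [trajectory_correlation()] over the trajectory's cells; a pair is
#' called when `r >= r_min` with BH `q <= q_max` (one BH family across
#' all trajectories). The union of per-trajectory calls is returned with
#' provenance.
#'
#' @param pairs A `pair_table`.
#' @param norm genes x cells normalised matrix.
#' @param cell_meta Tibble with `group` and `pseudotime` columns aligned
#'   to the matrix columns.
#' @param trajectories List of [trajectory_def()]s.
#' @param ordering_genes Named list (by trajectory name) of ordering-gene
#'   sets; computed with [select_ordering_genes()] upstream.
#' @param r_min,q_max Call thresholds (defaults 0.5 and 0.05).
#' @param require_both_dynamic Require both members in the trajectory's
#'   ordering set (default `TRUE`).
#' @param n_bins Pseudotime bins (default 20).
#' @return A tibble of class `hc_call_table` with one row per tested
#'   pair x trajectory: `trajectory`, `lnc_id`, `pcg_id`,
#'   `configuration`, `traj_r`, `traj_p`, `traj_q`, `called`.
#' @export
call_high_confidence <- function(pairs, norm, cell_meta, trajectories,
                                 ordering_genes, r_min = 0.5,
                                 q_max = 0.05,
                                 require_both_dynamic = TRUE,
                                 n_bins = 20) {
  stopifnot(all(c("group", "pseudotime") %in% names(cell_meta)),
            nrow(cell_meta) == ncol(norm))
  rows <- purrr::map_dfr(trajectories, function(tr) {
    idx <- which(cell_meta$group %in% tr$groups)
    keep <- pairs$lnc_id %in% rownames(norm) &
      pairs$pcg_id %in% rownames(norm)
    if (require_both_dynamic) {
      og <- ordering_genes[[tr$name]]
      keep <- keep & pairs$lnc_id %in% og & pairs$pcg_id %in% og
    }
    pr <- pairs[keep, , drop = FALSE]
    if (!nrow(pr)) return(NULL)
    sub <- as.matrix(norm[unique(c(pr$lnc_id, pr$pcg_id)), idx,
                          drop = FALSE])
    pt <- cell_meta$pseudotime[idx]
    res <- purrr::map2(pr$lnc_id, pr$pcg_id, function(a, b) {
      trajectory_correlation(sub[a, ], sub[b, ], pt, n_bins)
    })
    tibble::tibble(
      trajectory = tr$name,
      lnc_id = pr$lnc_id,
      pcg_id = pr$pcg_id,
      configuration = pr$configuration,
      traj_r = purrr::map_dbl(res, "r"),
      traj_p = purrr::map_dbl(res, "p"),
      defined = purrr::map_lgl(res, "defined")
    )
  })
  if (is.null(rows) || !nrow(rows)) {
    rows <- tibble::tibble(trajectory = character(), lnc_id = character(),
                           pcg_id = character(),
                           configuration = character(),
                           traj_r = numeric(), traj_p = numeric(),
                           defined = logical())
  }
  rows$traj_q <- NA_real_
  if (any(rows$defined)) {
    rows$traj_q[rows$defined] <- fdr_bh(rows$traj_p[rows$defined])
  }
  rows$called <- rows$defined & !is.na(rows$traj_q) &
    rows$traj_r >= r_min & rows$traj_q <= q_max
  structure(rows, class = c("hc_call_table", class(tibble::tibble())))
}
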