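#' Build a diffusion (smoothing) operator over cells
#'
#' Markov-affinity operator in the style of diffusion-based dropout
#' imputation: PCA of cells to `n_pcs` dimensions (deterministic sign
#' convention: the largest-magnitude loading of each component is made
#' positive), a k-nearest-neighbour Gaussian kernel with per-cell
#' bandwidth equal to the distance to the k-th neighbour, symmetrisation
#' `A = (K + K')/2`, and row normalisation to a transition matrix.
#'
#' @param norm genes x cells normalised matrix.
#' @param k Number of nearest neighbours (default 15).
#' @param t Default number of diffusion steps used by [impute()]
#'   (default 3).
#' @param n_pcs Number of principal components (default 30; capped at
#'   the data rank).
#' @param seed Stored for provenance; the construction is deterministic.
#' @return A list of class `diffusion_operator`: row-stochastic
#'   `transition` (cells x cells), `k`, `t`, `n_pcs`, `cell_ids`, `seed`.
#' @export
build_diffusion <- function(norm, k = 15, t = 3, n_pcs = 30, seed = 1) {
  n_cells <- ncol(norm)
  if (k >= n_cells) stop("k must be smaller than the number of cells")
  x <- t(as.matrix(norm))
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  d <- as.matrix(stats::dist(scores))
  kern <- matrix(0, n_cells, n_cells)
  for (i in seq_len(n_cells)) {
    ord <- order(d[i, ])
    nn <- ord[seq_len(k + 1)]     # self plus k neighbours
    sigma <- d[i, ord[k + 1]]
    if (sigma == 0) sigma <- .Machine$double.eps
    kern[i, nn] <- exp(-(d[i, nn] / sigma)^2)
  }
  a <- (kern + t(kern)) / 2
  trans <- a / rowSums(a)
  dimnames(trans) <- list(colnames(norm), colnames(norm))
  structure(list(transition = trans, k = k, t = t, n_pcs = n_pcs,
                 cell_ids = colnames(norm), seed = seed),
            class = "diffusion_operator")
}

#' @export
print.diffusion_operator <- function(x, ...) {
  cat("<diffusion_operator> ", length(x$cell_ids), " cells, k = ", x$k,
      ", t = ", x$t, ", n_pcs = ", x$n_pcs, "\n", sep = "")
  invisible(x)
}

#' Smooth (impute) expression with a diffusion operator
#'
#' Applies `t` steps of the Markov transition over cells:
#' `X_imp = X (M')^t` for a genes x cells matrix `X`. `t = 0` returns the
#' input unchanged; a constant gene is unchanged for any `t` because the
#' operator is row-stochastic.
#'
#' @param op A [build_diffusion()] operator built on the same cells.
#' @param norm genes x cells matrix (all genes, or any subset of rows).
#' @param t Number of diffusion steps (default: the operator's `t`).
#' @return Dense genes x cells matrix of smoothed values.
#' @export
impute <- function(op, norm, t = op$t) {
  stopifnot(inherits(op, "diffusion_operator"))
  if (ncol(norm) != length(op$cell_ids)) {
    stop("matrix has ", ncol(norm), " cells but the operator was built on ",
         length(op$cell_ids))
  }
  x <- as.matrix(norm)
  if (t == 0) return(x)
  mt <- t(op$transition)
  for (i in seq_len(t)) x <- x %*% mt
  dimnames(x) <- dimnames(as.matrix(norm))
  x
}

#' Pearson correlation with a t-test p-value
#'
#' Sample Pearson r with the two-sided p-value from
#' `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom (the classical
#' `cor.test` machinery). Degenerate input (fewer than 3 paired values or
#' zero variance) is flagged rather than tested.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list: `r`, `p`, `n`, `defined`.
#' @export
pearson_cor_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, defined = TRUE)
}

#' Correlate lncRNA-PCG pairs across cells
#'
#' One Pearson test per pair (per cell group when `groups` is supplied;
#' the pooled `"all"` rows are always emitted). BH q-values are computed
#' within the full family of defined tests. Pairs with a member absent
#' from the matrix are skipped with a warning.
#'
#' @param pairs A `pair_table`.
#' @param mat genes x cells matrix of expression values (raw-normalised
#'   or imputed; say which via `basis`).
#' @param basis Label recorded in the output: `"raw"` or `"imputed"`.
#' @param groups Optional per-cell group labels; adds per-group rows.
#' @return A tibble of class `pair_cor_table`: `lnc_id`, `pcg_id`,
#'   `configuration`, `cell_group`, `basis`, `n_cells`, `r`, `p`, `q`,
#'   `defined`.
#' @export
correlate_pairs <- function(pairs, mat, basis = c("raw", "imputed"),
                            groups = NULL) {
  basis <- match.arg(basis)
  present <- pairs$lnc_id %in% rownames(mat) &
    pairs$pcg_id %in% rownames(mat)
  if (any(!present)) {
    warning(sum(!present), " pair(s) skipped: member absent from matrix")
  }
  pr <- pairs[present, , drop = FALSE]
  grp_sets <- list(all = seq_len(ncol(mat)))
  if (!is.null(groups)) {
    stopifnot(length(groups) == ncol(mat))
    for (g in sort(unique(groups))) grp_sets[[g]] <- which(groups == g)
  }
  dense <- as.matrix(mat[unique(c(pr$lnc_id, pr$pcg_id)), , drop = FALSE])
  out <- purrr::map_dfr(names(grp_sets), function(gname) {
    idx <- grp_sets[[gname]]
    res <- purrr::map2(pr$lnc_id, pr$pcg_id, function(a, b) {
      pearson_cor_test(dense[a, idx], dense[b, idx])
    })
    tibble::tibble(
      lnc_id = pr$lnc_id,
      pcg_id = pr$pcg_id,
      configuration = pr$configuration,
      cell_group = gname,
      basis = basis,
      n_cells = length(idx),
      r = purrr::map_dbl(res, "r"),
      p = purrr::map_dbl(res, "p"),
      defined = purrr::map_lgl(res, "defined")
    )
  })
  out$q <- NA_real_
  out$q[out$defined] <- fdr_bh(out$p[out$defined])
  out <- out[, c("lnc_id", "pcg_id", "configuration", "cell_group",
                 "basis", "n_cells", "r", "p", "q", "defined")]
  structure(out, class = c("pair_cor_table", class(tibble::tibble())))
}

#' Per-configuration correlation summary
#'
#' Median pair correlation by configuration and cell group (the usual
#' per-category co-expression summary).
#'
#' @param cor_table A [correlate_pairs()] result.
#' @return Tibble with `configuration`, `cell_group`, `basis`,
#'   `n_pairs`, `median_r`.
#' @export
configuration_cor_summary <- function(cor_table) {
  cor_table |>
    dplyr::filter(.data$defined) |>
    dplyr::group_by(.data$configuration, .data$cell_group, .data$basis) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     median_r = stats::median(.data$r),
                     .groups = "drop")
}
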