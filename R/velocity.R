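#' Filter genes for velocity fitting
#'
#' Keeps genes carrying at least `min_shared` summed counts in the
#' spliced layer and at least `min_shared` in the unspliced layer.
#'
#' @param spliced,unspliced genes x cells count matrices with identical
#'   dimnames.
#' @param min_shared Count threshold per layer (default 20).
#' @return Character vector of retained gene ids.
#' @export
filter_velocity_genes <- function(spliced, unspliced, min_shared = 20) {
  stopifnot(identical(dim(spliced), dim(unspliced)))
  s <- Matrix::rowSums(spliced)
  u <- Matrix::rowSums(unspliced)
  rownames(spliced)[s >= min_shared & u >= min_shared]
}

#' Steady-state degradation/splicing ratio of one gene
#'
#' Least-squares slope through the origin of unspliced on spliced,
#' fitted on the cells in the bottom and top `q` quantiles of the
#' spliced values (the extreme-quantile steady-state fit).
#'
#' @param s,u Per-cell spliced and unspliced values of one gene.
#' @param q Extreme-quantile fraction (default 0.05).
#' @return Non-negative `gamma`; `NA` when the spliced vector is all
#'   zero (gene dropped upstream).
#' @export
fit_gamma <- function(s, u, q = 0.05) {
  stopifnot(length(s) == length(u))
  if (all(s == 0)) return(NA_real_)
  qs <- stats::quantile(s, c(q, 1 - q), names = FALSE)
  sel <- s <= qs[1] | s >= qs[2]
  if (sum(sel) < 10) sel <- rep(TRUE, length(s))
  ss <- s[sel]
  uu <- u[sel]
  denom <- sum(ss^2)
  if (denom == 0) return(NA_real_)
  max(0, sum(uu * ss) / denom)
}

#' Fit steady-state RNA velocity
#'
#' Per-cell library-size normalisation (counts-per-10k, no log) of both
#' layers, gene filtering by [filter_velocity_genes()], per-gene
#' [fit_gamma()], and the velocity matrix `v = u - gamma * s` with the
#' per-cell velocity length (L2 norm over the genes used).
#'
#' @param m A [cell_matrix()] with `spliced` and `unspliced` layers, or
#'   `NULL` when `spliced`/`unspliced` are given directly.
#' @param spliced,unspliced Optional explicit layer matrices.
#' @param min_shared Gene filter threshold (default 20).
#' @param fit_quantile Extreme-quantile fraction for the gamma fit.
#' @param normalize Per-cell CP10k normalisation of both layers before
#'   fitting (default `TRUE`).
#' @param scale CP10k target.
#' @param velocity_in Optional externally computed genes x cells
#'   velocity matrix; when supplied, only the velocity-length statistic
#'   is recomputed from it.
#' @return An object of class `velocity_fit`: `gamma` (named per-gene),
#'   `genes_used`, `velocity` (genes x cells), `velocity_length`
#'   (named per-cell), `fit_quantile`, `min_shared`.
#' @export
fit_velocity <- function(m = NULL, spliced = NULL, unspliced = NULL,
                         min_shared = 20, fit_quantile = 0.05,
                         normalize = TRUE, scale = 1e4,
                         velocity_in = NULL) {
  if (!is.null(velocity_in)) {
    v <- as.matrix(velocity_in)
    vl <- sqrt(colSums(v^2))
    return(structure(list(gamma = NULL, genes_used = rownames(v),
                          velocity = v, velocity_length = vl,
                          fit_quantile = fit_quantile,
                          min_shared = min_shared),
                     class = "velocity_fit"))
  }
  if (!is.null(m)) {
    stopifnot(inherits(m, "cell_matrix"))
    spliced <- m$layers$spliced
    unspliced <- m$layers$unspliced
    if (is.null(spliced) || is.null(unspliced)) {
      stop("cell_matrix has no spliced/unspliced layers")
    }
  }
  genes <- filter_velocity_genes(spliced, unspliced, min_shared)
  if (!length(genes)) stop("no genes pass min_shared = ", min_shared)
  cp10k <- function(x) {
    tot <- Matrix::colSums(x)
    sf <- ifelse(tot > 0, scale / tot, 0)
    as.matrix(x %*% Matrix::Diagonal(x = sf))
  }
  s_n <- if (normalize) cp10k(spliced) else as.matrix(spliced)
  u_n <- if (normalize) cp10k(unspliced) else as.matrix(unspliced)
  dimnames(s_n) <- dimnames(u_n) <- dimnames(spliced)
  s_n <- s_n[genes, , drop = FALSE]
  u_n <- u_n[genes, , drop = FALSE]
  gamma <- vapply(genes, function(g) {
    fit_gamma(s_n[g, ], u_n[g, ], q = fit_quantile)
  }, numeric(1))
  ok <- !is.na(gamma)
  gamma <- gamma[ok]
  genes <- genes[ok]
  v <- u_n[genes, , drop = FALSE] - gamma * s_n[genes, , drop = FALSE]
  vl <- sqrt(colSums(v^2))
  structure(list(gamma = gamma, genes_used = genes, velocity = v,
                 velocity_length = vl, fit_quantile = fit_quantile,
                 min_shared = min_shared),
            class = "velocity_fit")
}

#' @export
print.velocity_fit <- function(x, ...) {
  cat("<velocity_fit> ", length(x$genes_used), " genes x ",
      length(x$velocity_length), " cells\n", sep = "")
  invisible(x)
}

#' Per-cell velocity length
#'
#' L2 norm of the velocity vector over the genes used, per cell: the
#' scalar summarising how fast a cell's transcriptome is moving.
#'
#' @param fit A [fit_velocity()] object.
#' @return Named numeric vector (one value per cell, >= 0).
#' @export
velocity_length <- function(fit) {
  stopifnot(inherits(fit, "velocity_fit"))
  fit$velocity_length
}

#' Group-level velocity and abundance summary
#'
#' Per-group means of velocity length and total transcripts, with the
#' Spearman rank correlation between the two per-cell quantities
#' (within groups and globally).
#'
#' @param lengths Per-cell velocity lengths.
#' @param totals Per-cell total detected transcripts (e.g. total UMIs).
#' @param labels Per-cell group labels covering all cells.
#' @return Tibble with `group`, `n_cells`, `mean_velocity_length`,
#'   `mean_total`, `spearman_r`; the pooled Spearman correlation is in
#'   attribute `global_spearman`.
#' @export
group_velocity_summary <- function(lengths, totals, labels) {
  stopifnot(length(lengths) == length(totals),
            length(lengths) == length(labels))
  out <- tibble::tibble(group = labels, len = lengths, tot = totals) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_velocity_length = mean(.data$len),
      mean_total = mean(.data$tot),
      spearman_r = if (dplyr::n() > 2 && stats::sd(.data$len) > 0 &&
                       stats::sd(.data$tot) > 0) {
        stats::cor(.data$len, .data$tot, method = "spearman")
      } else NA_real_,
      .groups = "drop"
    )
  glob <- if (stats::sd(lengths) > 0 && stats::sd(totals) > 0) {
    stats::cor(lengths, totals, method = "spearman")
  } else NA_real_
  attr(out, "global_spearman") <- glob
  out
}
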