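#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a velocity fit
#'
#' One row per gene used by the fit: the steady-state
#' degradation/splicing ratio and the mean spliced/unspliced signal.
#'
#' @param x A [fit_velocity()] object.
#' @param ... Unused.
#' @return A tibble with `gene_id`, `gamma`, `mean_velocity`.
#' @export
tidy.velocity_fit <- function(x, ...) {
  tibble::tibble(
    gene_id = x$genes_used,
    gamma = if (is.null(x$gamma)) NA_real_ else unname(x$gamma),
    mean_velocity = rowMeans(x$velocity)
  )
}

#' @rdname tidy.velocity_fit
#' @return For `glance`: a one-row tibble with `n_genes`, `n_cells`,
#'   `median_gamma`, `mean_velocity_length`.
#' @export
glance.velocity_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes_used),
    n_cells = length(x$velocity_length),
    median_gamma = if (is.null(x$gamma)) NA_real_ else
      stats::median(x$gamma),
    mean_velocity_length = mean(x$velocity_length)
  )
}

#' Tidy a lncRNA expression atlas
#'
#' @param x A [cluster_lnc_profiles()] object.
#' @param ... Unused.
#' @return The gene-to-cluster assignment tibble (`tidy`) or a one-row
#'   summary (`glance`).
#' @export
tidy.lnc_atlas <- function(x, ...) x$atlas

#' @rdname tidy.lnc_atlas
#' @export
glance.lnc_atlas <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$atlas), k = x$k, seed = x$seed)
}

#' Tidy a diffusion operator
#'
#' @param x A [build_diffusion()] operator.
#' @param ... Unused.
#' @return For `glance`: one row with `n_cells`, `k`, `t`, `n_pcs`.
#' @export
glance.diffusion_operator <- function(x, ...) {
  tibble::tibble(n_cells = length(x$cell_ids), k = x$k, t = x$t,
                 n_pcs = x$n_pcs)
}
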