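#' Pipeline configuration
#'
#' Collects every stage's settings with the study defaults as named
#' values: QC thresholds, 5-kb pairing window, marker contrasts,
#' diffusion-operator settings, trajectory definitions with ordering-gene
#' thresholds (fold change 2, adjusted p 0.05, top 20% expression),
#' high-confidence call criteria, and the velocity block.
#'
#' @param gtf,counts_dir,cell_meta Input paths (GTF, MTX triplet
#'   directory, cell-metadata TSV).
#' @param spliced_dir,unspliced_dir Optional MTX triplet directories for
#'   the velocity layers.
#' @param out_dir Output directory.
#' @param qc A [qc_thresholds()].
#' @param window_bp,pair_mode Pairing block.
#' @param scale Normalisation library-size target.
#' @param contrasts List of 2-vectors of cell types for marker tables.
#' @param knn_k,diff_t,n_pcs Diffusion-operator block.
#' @param trajectories List of [trajectory_def()]s (groups are
#'   `celltype_stage` labels).
#' @param log2fc_min,traj_q_max,top_expr_frac Ordering-gene rule.
#' @param r_min,hc_q_max,require_both_dynamic,n_bins High-confidence
#'   call block.
#' @param min_shared,fit_quantile,velocity_normalize Velocity block.
#' @param seed Master seed propagated to every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(gtf, counts_dir, cell_meta,
                            spliced_dir = NULL, unspliced_dir = NULL,
                            out_dir = tempfile("lncpair_run"),
                            qc = qc_thresholds(),
                            window_bp = 5000,
                            pair_mode = "distance",
                            scale = 1e4,
                            contrasts = list(c("CTB", "STB"),
                                             c("CTB", "EVT"),
                                             c("STB", "EVT")),
                            knn_k = 15, diff_t = 3, n_pcs = 30,
                            trajectories = list(
                              trajectory_def("CTB_maturation",
                                             c("CTB_early", "CTB_late")),
                              trajectory_def("CTB_to_EVT",
                                             c("CTB_early", "CTB_late",
                                               "EVT_early", "EVT_late")),
                              trajectory_def("CTB_to_STB",
                                             c("CTB_early", "CTB_late",
                                               "STB_early", "STB_late"))),
                            log2fc_min = 2, traj_q_max = 0.05,
                            top_expr_frac = 0.2,
                            r_min = 0.5, hc_q_max = 0.05,
                            require_both_dynamic = TRUE, n_bins = 20,
                            min_shared = 20, fit_quantile = 0.05,
                            velocity_normalize = TRUE,
                            seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level YAML keys are passed as arguments to [pipeline_config()];
#' `qc` blocks become [qc_thresholds()] and `trajectories` entries
#' (`name`, `groups`) become [trajectory_def()]s.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$qc)) y$qc <- do.call(qc_thresholds, y$qc)
  if (!is.null(y$trajectories)) {
    y$trajectories <- lapply(y$trajectories, function(tr) {
      trajectory_def(tr$name, unlist(tr$groups))
    })
  }
  do.call(pipeline_config, y)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(cfg), unclass, how = "replace")
  plain$out_dir <- NULL              # output location is not an input
  yaml::write_yaml(plain, tmp)
  unname(tools::md5sum(tmp))
}

write_output_tsv <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.factor(df[[nm]])) df[[nm]] <- as.character(df[[nm]])
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — annotation, QC, pair
#' discovery, markers, pair correlation (raw and imputed bases),
#' trajectory calling, velocity — writing one TSV per result plus a JSON
#' run manifest. Every output carries a header comment with the package
#' version, the config hash and the seed; a rerun with the same inputs
#' and seed is byte-identical.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the stage results and `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  hdr <- c(paste0("lncpair ", utils::packageVersion("lncpair")),
           paste0("config_hash ", hash),
           paste0("seed ", cfg$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  stages <- character()
  res <- list()

  ann <- stage("annotation", read_gtf(cfg$gtf))
  stages <- c(stages, "annotation")

  qc_res <- stage("qc", {
    m <- read_mtx_triplet(cfg$counts_dir, cell_meta = cfg$cell_meta)
    if (!is.null(cfg$spliced_dir) && !is.null(cfg$unspliced_dir)) {
      sp <- read_mtx_triplet(cfg$spliced_dir)
      un <- read_mtx_triplet(cfg$unspliced_dir)
      m <- cell_matrix(m$counts, cell_meta = m$cell_meta,
                       gene_meta = m$gene_meta,
                       layers = list(spliced = sp$counts,
                                     unspliced = un$counts))
    }
    apply_qc(m, cfg$qc)
  })
  stages <- c(stages, "qc")
  write_output_tsv(qc_res$cell_qc, file.path(cfg$out_dir, "qc_cells.tsv"),
                   hdr)
  write_output_tsv(qc_res$removed,
                   file.path(cfg$out_dir, "qc_removed.tsv"), hdr)
  m <- qc_res$matrix
  bio <- biotype_fraction(m, ann)
  write_output_tsv(bio, file.path(cfg$out_dir, "biotype_fractions.tsv"),
                   hdr)

  pairs <- stage("pairs", find_proximal_pairs(ann, cfg$window_bp,
                                              cfg$pair_mode))
  stages <- c(stages, "pairs")
  write_output_tsv(pairs, file.path(cfg$out_dir, "pairs.tsv"), hdr)
  write_output_tsv(configuration_frequencies(pairs),
                   file.path(cfg$out_dir, "pair_config_frequencies.tsv"),
                   hdr)

  norm <- normalize_log(m, cfg$scale)
  marker_tabs <- stage("markers", {
    lapply(cfg$contrasts, function(ct) {
      find_markers(norm, m$cell_meta$cell_type, ct[1], ct[2])
    })
  })
  stages <- c(stages, "markers")
  for (i in seq_along(marker_tabs)) {
    ct <- cfg$contrasts[[i]]
    write_output_tsv(marker_tabs[[i]], file.path(
      cfg$out_dir, sprintf("markers_%s_vs_%s.tsv", ct[1], ct[2])), hdr)
  }

  cors <- stage("correlation", {
    pair_genes <- unique(c(pairs$lnc_id, pairs$pcg_id))
    pair_genes <- intersect(pair_genes, rownames(norm))
    op <- build_diffusion(norm, k = cfg$knn_k, t = cfg$diff_t,
                          n_pcs = cfg$n_pcs, seed = cfg$seed)
    imp <- impute(op, norm[pair_genes, , drop = FALSE])
    dplyr::bind_rows(
      correlate_pairs(pairs, norm, basis = "raw",
                      groups = m$cell_meta$cell_type),
      correlate_pairs(pairs, imp, basis = "imputed",
                      groups = m$cell_meta$cell_type)
    )
  })
  stages <- c(stages, "correlation")
  write_output_tsv(cors, file.path(cfg$out_dir, "pair_correlations.tsv"),
                   hdr)
  write_output_tsv(configuration_cor_summary(cors),
                   file.path(cfg$out_dir, "pair_cor_summary.tsv"), hdr)

  calls <- stage("trajectory", {
    if (!"pseudotime" %in% names(m$cell_meta)) {
      stop("cell metadata has no pseudotime column")
    }
    meta <- m$cell_meta
    meta$group <- paste(meta$cell_type, meta$stage, sep = "_")
    ordering <- lapply(cfg$trajectories, function(tr) {
      idx <- which(meta$group %in% tr$groups)
      ends <- c(tr$groups[1], tr$groups[length(tr$groups)])
      mk <- find_markers(norm[, idx, drop = FALSE], meta$group[idx],
                         ends[2], ends[1])
      mu <- rowMeans(expm1(as.matrix(norm[, idx, drop = FALSE])))
      select_ordering_genes(mk, mu, cfg$log2fc_min, cfg$traj_q_max,
                            cfg$top_expr_frac)
    })
    names(ordering) <- vapply(cfg$trajectories, `[[`, "", "name")
    call_high_confidence(pairs, norm, meta, cfg$trajectories, ordering,
                         r_min = cfg$r_min, q_max = cfg$hc_q_max,
                         require_both_dynamic = cfg$require_both_dynamic,
                         n_bins = cfg$n_bins)
  })
  stages <- c(stages, "trajectory")
  write_output_tsv(calls, file.path(cfg$out_dir, "trajectory_calls.tsv"),
                   hdr)

  vel_summary <- NULL
  if (!is.null(m$layers$spliced) && !is.null(m$layers$unspliced)) {
    vel_summary <- stage("velocity", {
      fit <- fit_velocity(m, min_shared = cfg$min_shared,
                          fit_quantile = cfg$fit_quantile,
                          normalize = cfg$velocity_normalize)
      qc_tab <- compute_cell_qc(m)
      group_velocity_summary(velocity_length(fit), qc_tab$total_umi,
                             m$cell_meta$group %||%
                               paste(m$cell_meta$cell_type,
                                     m$cell_meta$stage, sep = "_"))
    })
    stages <- c(stages, "velocity")
    write_output_tsv(vel_summary,
                     file.path(cfg$out_dir, "velocity_summary.tsv"), hdr)
  }

  manifest <- list(
    tool = "lncpair",
    version = as.character(utils::packageVersion("lncpair")),
    seed = cfg$seed,
    config_hash = hash,
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(out_dir = cfg$out_dir, annotation = ann, qc = qc_res,
                 pairs = pairs, markers = marker_tabs,
                 correlations = cors, calls = calls,
                 velocity_summary = vel_summary, manifest = manifest))
}
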