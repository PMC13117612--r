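#' Configuration of the synthetic study
#'
#' One object holds every knob of the generator: the planted pair
#' geometry, the negative-binomial count model over the six trophoblast
#' groups (CTB/STB/EVT x early/late), planted pair correlations, the QC
#' failure plan, and the two-state transcription/splicing/degradation
#' kinetics for the spliced/unspliced layers. All outputs are fully
#' determined by `seed`.
#'
#' Defaults emulate the study conditions: planted configuration
#' proportions ranking XH most frequent and XO rarest, a lncRNA UMI share
#' of 3.47%, six groups of 500 nuclei, and 21 regulatory pairs whose
#' members ramp along their trajectory. The QC gene-count bounds are
#' panel-scaled (the ~1,500-gene synthetic panel cannot reach
#' whole-transcriptome detection counts); [qc_thresholds()] defaults keep
#' the full-transcriptome values.
#'
#' @param seed Integer master seed.
#' @param n_chroms Autosome count used for pair placement.
#' @param n_pairs Number of planted lncRNA-PCG pairs.
#' @param config_proportions Named proportions over the six
#'   configurations (sum to 1); realised counts use largest remainders.
#' @param window_bp Pairing window; planted gaps stay below it and
#'   inter-block spacing stays above it.
#' @param spacing_bp Distance between planted blocks (> window_bp).
#' @param n_extra_pcgs,n_extra_lncs,n_mito Unpaired background genes and
#'   mitochondrial genes (placed on chrM, names prefixed `MT-`).
#' @param cell_types,stages Group factors (six groups by default).
#' @param n_cells_per_group Nuclei per group.
#' @param mean_umi_per_cell Expected library size of a clean nucleus.
#' @param lnc_umi_share,mito_umi_share Expected UMI share of lncRNA and
#'   mitochondrial genes.
#' @param nb_size Negative-binomial size (inverse dispersion).
#' @param dropout_rate Independent per-entry zero-inflation probability.
#' @param n_regulatory Number of planted regulatory pairs (assigned
#'   round-robin to the trajectories); defaults to `min(21, n_pairs)`.
#' @param regulatory_latent_r Latent copula correlation of regulatory
#'   pairs, carried by the smooth manifold coordinate.
#' @param distractor_latent_r Latent correlation of the remaining pairs,
#'   carried by a cell-intrinsic factor (positively co-expressed but not
#'   trajectory-dynamic).
#' @param regulatory_fold Endpoint fold change of the regulatory ramp.
#' @param regulatory_expr_boost Multiplier putting regulatory genes in
#'   the high-expression tier (ordering genes are highly expressed).
#' @param marker_frac Fraction of background genes given a group-specific
#'   archetype.
#' @param marker_fold Archetype fold change.
#' @param n_doublets Planted doublets (sums of two clean cells, doublet
#'   score above 0.5).
#' @param qc_fail_plan Named counts of planted single-rule QC failures
#'   (`umi_low`, `umi_high`, `genes_low`, `genes_high`, `mito`).
#' @param qc [qc_thresholds()] the planted failures are defined against.
#' @param pseudotime_base Named per-group pseudotime offsets.
#' @param pseudotime_jitter Uniform jitter width added to the offset.
#' @param trajectories List of [trajectory_def()]s.
#' @param noiseless When `TRUE`, counts are the rounded expected values
#'   (no sampling, no copula, no dropout): the zero-noise limit.
#' @param kinetics List: `alpha_range`, `beta`, `gamma`, `nb_size`, and
#'   `phases` (named per-group `"induction"`, `"steady"`,
#'   `"repression"`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1,
    n_chroms = 4,
    n_pairs = 100,
    config_proportions = c(XH = 0.34, XT = 0.20, XI = 0.16,
                           XO = 0.02, SU = 0.14, SD = 0.14),
    window_bp = 5000,
    spacing_bp = 50000,
    n_extra_pcgs = 800,
    n_extra_lncs = 487,
    n_mito = 13,
    cell_types = c("CTB", "STB", "EVT"),
    stages = c("early", "late"),
    n_cells_per_group = 500,
    mean_umi_per_cell = 8000,
    lnc_umi_share = 0.0347,
    mito_umi_share = 0.01,
    nb_size = 2,
    dropout_rate = 0,
    n_regulatory = NULL,
    regulatory_latent_r = 0.8,
    distractor_latent_r = 0.5,
    regulatory_fold = 12,
    regulatory_expr_boost = 3,
    marker_frac = 0.3,
    marker_fold = 5,
    dynamic_frac = 0.35,
    dynamic_max_log2_fold = 2,
    n_doublets = 20,
    qc_fail_plan = c(umi_low = 10, umi_high = 5, genes_low = 5,
                     genes_high = 5, mito = 10),
    qc = qc_thresholds(genes_min = 200, genes_max = 1450),
    pseudotime_base = c(CTB_early = 0, CTB_late = 1, STB_early = 2,
                        STB_late = 3, EVT_early = 2, EVT_late = 3),
    pseudotime_jitter = 0.8,
    trajectories = list(
      trajectory_def("CTB_maturation", c("CTB_early", "CTB_late")),
      trajectory_def("CTB_to_EVT",
                     c("CTB_early", "CTB_late", "EVT_early", "EVT_late")),
      trajectory_def("CTB_to_STB",
                     c("CTB_early", "CTB_late", "STB_early", "STB_late"))
    ),
    noiseless = FALSE,
    kinetics = list(
      alpha_range = c(20, 100), beta = 1, gamma = 0.3, nb_size = 100,
      size_factor_sd = 0.25,
      phases = c(CTB_early = "induction", CTB_late = "steady",
                 STB_early = "steady", STB_late = "repression",
                 EVT_early = "induction", EVT_late = "repression")
    )) {
  if (is.null(n_regulatory)) n_regulatory <- min(21L, n_pairs)
  stopifnot(abs(sum(config_proportions) - 1) < 1e-8,
            all(names(config_proportions) %in% CONFIGURATIONS),
            spacing_bp > window_bp,
            n_regulatory <= n_pairs)
  cfg <- as.list(environment())
  cfg$groups <- as.vector(outer(cell_types, stages, paste, sep = "_"))
  structure(cfg, class = "sim_config")
}

# Largest-remainder apportionment of n into proportions p.
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

#' Simulate an annotation with planted pair configurations
#'
#' Places `n_pairs` lncRNA-PCG blocks whose configurations are certified
#' by construction (e.g. XI lncRNAs strictly inside an intron on the
#' antisense strand), separated by more than the pairing window so no
#' accidental pairs arise, plus unpaired background genes and
#' mitochondrial genes on chrM.
#'
#' @param cfg A [sim_config()].
#' @return A list: `annotation` (an `lnc_annotation`) and `pairs` (truth
#'   tibble with `lnc_id`, `pcg_id`, `chrom`, `configuration`,
#'   `regulatory`, `trajectory`, `latent_r`).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 11L, simulate_annotation_impl(cfg))
}

simulate_annotation_impl <- function(cfg) {
  n_per <- apportion(cfg$n_pairs, cfg$config_proportions)
  configs <- rep(names(n_per), n_per)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  cursor <- stats::setNames(rep(20000L, cfg$n_chroms), chroms)
  exon_len <- 500L

  genes <- list()
  pair_rows <- list()
  add_gene <- function(id, name, chrom, strand, start, end, biotype,
                       exons = NULL) {
    if (is.null(exons)) {
      exons <- matrix(c(start, end), ncol = 2,
                      dimnames = list(NULL, c("start", "end")))
    }
    genes[[length(genes) + 1]] <<- tibble::tibble(
      gene_id = id, gene_name = name, chrom = chrom, strand = strand,
      start = as.integer(start), end = as.integer(end), biotype = biotype,
      exons = list(exons)
    )
  }

  for (i in seq_along(configs)) {
    cf <- configs[i]
    chr <- chroms[((i - 1) %% cfg$n_chroms) + 1]
    pcg_len <- sample(8000:20000, 1)
    lnc_len <- sample(400:1500, 1)
    gap <- sample(100:(cfg$window_bp - 100), 1)
    a <- cursor[chr] + 10000L            # room upstream for the lncRNA
    b <- a + pcg_len - 1L
    pstrand <- sample(c("+", "-"), 1)
    pcg_ex <- rbind(c(a, a + exon_len - 1L), c(b - exon_len + 1L, b))
    colnames(pcg_ex) <- c("start", "end")
    anti <- if (pstrand == "+") "-" else "+"
    pcg_id <- sprintf("PCG%04d", i)
    lnc_id <- sprintf("LNC%04d", i)
    add_gene(pcg_id, pcg_id, chr, pstrand, a, b, "protein_coding", pcg_ex)

    place <- function(left) {
      # span of length lnc_len with the given left coordinate
      c(left, left + lnc_len - 1L)
    }
    # orientation helpers: the pcg TSS-side is `a` on + and `b` on -
    at_tss_side <- pstrand == "+"
    span <- switch(cf,
      XH = if (at_tss_side) place(a - gap - lnc_len) else place(b + gap),
      XT = if (at_tss_side) place(b + gap) else place(a - gap - lnc_len),
      SU = if (at_tss_side) place(a - gap - lnc_len) else place(b + gap),
      SD = if (at_tss_side) place(b + gap) else place(a - gap - lnc_len),
      XI = {
        intron <- c(a + exon_len, b - exon_len)
        if (diff(intron) < lnc_len + 400L) {
          stop("infeasible geometry: intron too short for XI lncRNA")
        }
        left <- sample((intron[1] + 200L):(intron[2] - 200L - lnc_len), 1)
        c(left, left + lnc_len - 1L)
      },
      XO = {
        # overlap the 5'-most exon by construction
        left <- a + 50L
        c(left, left + lnc_len - 1L)
      }
    )
    lstrand <- if (cf %in% c("SU", "SD")) pstrand else anti
    add_gene(lnc_id, lnc_id, chr, lstrand, span[1], span[2], "lncRNA")
    pair_rows[[i]] <- tibble::tibble(
      lnc_id = lnc_id, pcg_id = pcg_id, chrom = chr, configuration = cf
    )
    cursor[chr] <- max(b, span[2]) + cfg$spacing_bp
  }

  for (j in seq_len(cfg$n_extra_pcgs)) {
    chr <- chroms[((j - 1) %% cfg$n_chroms) + 1]
    len <- sample(3000:15000, 1)
    a <- cursor[chr] + 10000L
    id <- sprintf("BGP%04d", j)
    add_gene(id, id, chr, sample(c("+", "-"), 1), a, a + len - 1L,
             "protein_coding")
    cursor[chr] <- a + len + cfg$spacing_bp
  }
  for (j in seq_len(cfg$n_extra_lncs)) {
    chr <- chroms[((j - 1) %% cfg$n_chroms) + 1]
    len <- sample(400:3000, 1)
    a <- cursor[chr] + 10000L
    id <- sprintf("BGL%04d", j)
    add_gene(id, id, chr, sample(c("+", "-"), 1), a, a + len - 1L,
             "lncRNA")
    cursor[chr] <- a + len + cfg$spacing_bp
  }
  mito_names <- paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "ATP8",
                                "ATP6", "CO3", "ND3", "ND4L", "ND4",
                                "ND5", "ND6", "CYB"))
  for (j in seq_len(cfg$n_mito)) {
    a <- 1000L + (j - 1L) * 1200L
    id <- sprintf("MTG%02d", j)
    add_gene(id, mito_names[((j - 1) %% 13) + 1], "chrM", "+",
             a, a + 900L, "protein_coding")
  }

  ann <- new_annotation(dplyr::bind_rows(genes),
                        chrom_order = c(chroms, "chrM"))
  pairs <- dplyr::bind_rows(pair_rows)

  # regulatory assignment: round-robin over trajectories, spread across
  # configurations by taking every k-th pair
  pairs$regulatory <- FALSE
  pairs$trajectory <- NA_character_
  if (cfg$n_regulatory > 0) {
    idx <- unique(round(seq(1, nrow(pairs), length.out = cfg$n_regulatory)))
    while (length(idx) < cfg$n_regulatory) {
      idx <- union(idx, sample(setdiff(seq_len(nrow(pairs)), idx), 1))
    }
    idx <- sort(idx)[seq_len(cfg$n_regulatory)]
    pairs$regulatory[idx] <- TRUE
    tnames <- vapply(cfg$trajectories, `[[`, "", "name")
    pairs$trajectory[idx] <- tnames[((seq_along(idx) - 1) %%
                                       length(tnames)) + 1]
  }
  pairs$latent_r <- ifelse(pairs$regulatory, cfg$regulatory_latent_r,
                           cfg$distractor_latent_r)
  list(annotation = ann, pairs = pairs)
}

#' Simulate per-cell pseudotime and group assignment
#'
#' Cells get `group base + uniform jitter`, monotone in each
#' trajectory's lineage order.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with `cell_id`, `cell_type`, `stage`, `group`,
#'   `pseudotime`.
#' @export
simulate_pseudotime <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 23L, {
    cells <- tidyr::expand_grid(
      cell_type = cfg$cell_types, stage = cfg$stages,
      rep = seq_len(cfg$n_cells_per_group)
    ) |>
      dplyr::mutate(
        group = paste(.data$cell_type, .data$stage, sep = "_"),
        cell_id = sprintf("cell_%s_%04d", .data$group, .data$rep),
        pseudotime = cfg$pseudotime_base[.data$group] +
          stats::runif(dplyr::n(), 0, cfg$pseudotime_jitter)
      ) |>
      dplyr::select("cell_id", "cell_type", "stage", "group",
                    "pseudotime")
    cells
  })
}

#' Simulate a single-nucleus count matrix with ground truth
#'
#' Negative-binomial counts per gene x group with planted structure:
#' group-specific archetype genes, regulatory pairs that ramp along their
#' trajectory and share a smooth latent copula factor, distractor pairs
#' sharing a cell-intrinsic latent factor, a controlled lncRNA UMI share,
#' mitochondrial content, planned single-rule QC failures, doublets, and
#' optional dropout.
#'
#' @param cfg A [sim_config()].
#' @param sim_ann A [simulate_annotation()] result.
#' @return A list: `matrix` (a [cell_matrix()] with full `cell_meta`) and
#'   `truth` (list of tibbles `genes`, `pairs` — with `realized_r`
#'   measured on the pre-dropout counts — and `cells` with the planned
#'   failure labels).
#' @export
simulate_counts <- function(cfg, sim_ann) {
  stopifnot(inherits(cfg, "sim_config"))
  cells <- simulate_pseudotime(cfg)
  withr::with_seed(cfg$seed + 37L,
                   simulate_counts_impl(cfg, sim_ann, cells))
}

simulate_counts_impl <- function(cfg, sim_ann, cells) {
  ann <- sim_ann$annotation
  pairs <- sim_ann$pairs
  genes <- ann$gene_id
  n_genes <- length(genes)
  n_cells <- nrow(cells)
  groups <- cfg$groups
  biotype <- ann$biotype
  is_mito <- startsWith(ann$gene_name, "MT-")

  # heavily skewed base expression, as in real transcriptomes;
  # mitochondrial genes are uniformly high housekeeping transcripts, so
  # their spread is kept tight (keeps per-cell mito fractions stable)
  base_mu <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1.5)
  base_mu[is_mito] <- stats::rlnorm(sum(is_mito), meanlog = 0,
                                    sdlog = 0.5)
  names(base_mu) <- genes

  # archetype assignment for background genes (group-specific programs)
  archetype <- rep(NA_character_, n_genes)
  names(archetype) <- genes
  bg <- which(startsWith(genes, "BG"))
  n_marked <- round(cfg$marker_frac * length(bg))
  if (n_marked > 0) {
    marked <- sample(bg, n_marked)
    archetype[marked] <- sample(groups, n_marked, replace = TRUE)
  }

  # per-gene x group multipliers
  mult <- matrix(1, n_genes, length(groups),
                 dimnames = list(genes, groups))
  for (i in which(!is.na(archetype))) {
    mult[i, archetype[i]] <- cfg$marker_fold
  }
  # smoothly pseudotime-responsive background genes: the differentiation
  # continuum is encoded across many genes, as in real transcriptomes
  dyn_slope <- rep(0, n_genes)
  pool <- setdiff(bg, which(!is.na(archetype)))
  n_dyn <- round(cfg$dynamic_frac * length(bg))
  if (n_dyn > 0 && length(pool)) {
    dyn <- sample(pool, min(n_dyn, length(pool)))
    dyn_slope[dyn] <- stats::runif(length(dyn), -1, 1) *
      cfg$dynamic_max_log2_fold
    pt_base <- cfg$pseudotime_base[groups]
    pt_scaled <- (pt_base - mean(range(pt_base))) / diff(range(pt_base)) * 2
    for (i in dyn) {
      mult[i, ] <- mult[i, ] * 2 ^ (dyn_slope[i] * pt_scaled)
    }
  }
  reg <- pairs[pairs$regulatory, , drop = FALSE]
  tr_by_name <- stats::setNames(cfg$trajectories,
                                vapply(cfg$trajectories, `[[`, "", "name"))
  if (nrow(reg)) {
    # regulatory pair members are planted as highly expressed genes of
    # their biotype (top of class), like the well-expressed lncRNAs that
    # drive trajectory ordering in real data
    q_cls <- c(
      lncRNA = stats::quantile(base_mu[biotype == "lncRNA"], 0.975,
                               names = FALSE),
      protein_coding = stats::quantile(
        base_mu[biotype == "protein_coding" & !is_mito], 0.975,
        names = FALSE)
    )
    for (i in seq_len(nrow(reg))) {
      tr <- tr_by_name[[reg$trajectory[i]]]
      ramp <- cfg$regulatory_fold ^
        (seq(0, 1, length.out = length(tr$groups)))
      for (g in c(reg$lnc_id[i], reg$pcg_id[i])) {
        base_mu[g] <- q_cls[[biotype[match(g, genes)]]] *
          cfg$regulatory_expr_boost
        mult[g, tr$groups] <- ramp
      }
    }
  }

  # per-group class scaling: every group hits the exact lncRNA and
  # mitochondrial UMI shares and the same expected library size, so
  # planted fold changes never drag a whole group across QC bounds
  cls <- ifelse(is_mito, "mito",
                ifelse(biotype == "lncRNA", "lnc", "pcg"))
  share <- c(lnc = cfg$lnc_umi_share, mito = cfg$mito_umi_share)
  share["pcg"] <- 1 - sum(share)
  mug <- mult * base_mu                  # genes x groups expectation
  for (g in seq_along(groups)) {
    for (cl in names(share)) {
      rows <- cls == cl
      tot_cl <- sum(mug[rows, g])
      if (tot_cl > 0) {
        mug[rows, g] <- mug[rows, g] *
          (share[cl] * cfg$mean_umi_per_cell / tot_cl)
      }
    }
  }

  # expected value per gene x cell
  mu <- mug[, match(cells$group, groups), drop = FALSE]
  dimnames(mu) <- list(genes, cells$cell_id)
  # dynamic genes also track the cell's position within its group (the
  # differentiation continuum is continuous, not a step function);
  # within-group centring keeps expected library sizes at their target
  dyn_rows <- which(dyn_slope != 0)
  if (length(dyn_rows)) {
    pt_centred <- cells$pseudotime -
      stats::ave(cells$pseudotime, cells$group)
    for (i in dyn_rows) {
      mu[i, ] <- mu[i, ] * 2 ^ (dyn_slope[i] * pt_centred)
    }
    # re-pin every cell's expected library size and mito share, which
    # the modulation would otherwise perturb; a no-op on the CP10k
    # scale the downstream analysis works on
    nonmito <- which(!is_mito)
    tot_nm <- colSums(mu[nonmito, , drop = FALSE])
    f <- cfg$mean_umi_per_cell * (1 - cfg$mito_umi_share) / tot_nm
    mu[nonmito, ] <- sweep(mu[nonmito, , drop = FALSE], 2, f, `*`)
  }

  # mean-dependent dispersion: relative overdispersion shrinks for
  # high-expression genes, as in real UMI data (var = mu + mu^2/size)
  size_of <- function(mu) cfg$nb_size + mu / 20
  if (cfg$noiseless) {
    counts <- round(mu)
  } else {
    counts <- matrix(
      stats::rnbinom(length(mu), size = size_of(as.numeric(mu)),
                     mu = as.numeric(mu)),
      n_genes, n_cells, dimnames = dimnames(mu)
    )
    # planted copula correlations; the latent is standardised within each
    # group so the planted group means (library sizes, biotype shares)
    # are the NB marginals exactly
    m_coord <- stats::qnorm((rank(cells$pseudotime, ties.method = "first") -
                               0.5) / n_cells)
    grp_idx <- split(seq_len(n_cells), cells$group)
    std_by_group <- function(z) {
      for (idx in grp_idx) {
        s <- stats::sd(z[idx])
        z[idx] <- (z[idx] - mean(z[idx])) / (if (s > 0) s else 1)
      }
      z
    }
    for (i in seq_len(nrow(pairs))) {
      r <- pairs$latent_r[i]
      shared <- if (pairs$regulatory[i]) m_coord else stats::rnorm(n_cells)
      for (g in c(pairs$lnc_id[i], pairs$pcg_id[i])) {
        z <- std_by_group(sqrt(r) * shared +
                            sqrt(1 - r) * stats::rnorm(n_cells))
        counts[g, ] <- stats::qnbinom(stats::pnorm(z),
                                      size = size_of(mu[g, ]),
                                      mu = mu[g, ])
      }
    }
  }

  # realized pair correlations on the clean, pre-dropout counts
  pairs$realized_r <- vapply(seq_len(nrow(pairs)), function(i) {
    x <- counts[pairs$lnc_id[i], ]
    y <- counts[pairs$pcg_id[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))

  if (!cfg$noiseless && cfg$dropout_rate > 0) {
    mask <- matrix(stats::rbinom(length(counts), 1,
                                 1 - cfg$dropout_rate),
                   n_genes, n_cells)
    counts <- counts * mask
  }

  # planned QC failures, one rule per planted cell
  plan <- cfg$qc_fail_plan
  plan <- plan[plan > 0]
  planned_fail <- rep("none", n_cells)
  if (isTRUE(plan["genes_high"] > 0) && n_genes <= cfg$qc$genes_max) {
    stop("infeasible QC plan: genes_high failures need more genes (",
         n_genes, ") than genes_max (", cfg$qc$genes_max, ")")
  }
  if (length(plan) && !cfg$noiseless) {
    victims <- sample(n_cells, sum(plan))
    lab <- rep(names(plan), plan)
    planned_fail[victims] <- lab
    t <- cfg$qc
    for (j in seq_along(victims)) {
      cidx <- victims[j]
      v <- counts[, cidx]
      tot <- sum(v)
      v <- switch(lab[j],
        umi_low = stats::rbinom(n_genes, v,
                                min(1, (t$umi_min * 0.5) / max(tot, 1))),
        umi_high = v * (ceiling(1.2 * t$umi_max / max(tot, 1))),
        genes_low = {
          keep <- order(v, decreasing = TRUE)[seq_len(
            max(1, floor(t$genes_min / 2)))]
          w <- rep(0, n_genes)
          w[keep] <- v[keep] * ceiling(tot / max(sum(v[keep]), 1))
          w
        },
        genes_high = v + 1,
        mito = {
          add <- ceiling(0.10 * tot)
          v[which(is_mito)[1]] <- v[which(is_mito)[1]] + add
          v
        }
      )
      counts[, cidx] <- v
    }
  }

  # doublets: sums of two clean cells, appended
  cells$planned_fail <- planned_fail
  cells$is_doublet <- FALSE
  cells$doublet_score <- stats::runif(n_cells, 0.01, 0.40)
  if (cfg$n_doublets > 0 && !cfg$noiseless) {
    clean <- which(planned_fail == "none")
    dbl_cols <- matrix(0, n_genes, cfg$n_doublets)
    dbl_meta <- list()
    for (j in seq_len(cfg$n_doublets)) {
      ab <- sample(clean, 2)
      v <- counts[, ab[1]] + counts[, ab[2]]
      tries <- 0
      while (sum(v > 0) > cfg$qc$genes_max && tries < 20) {
        ab <- sample(clean, 2)
        v <- counts[, ab[1]] + counts[, ab[2]]
        tries <- tries + 1
      }
      dbl_cols[, j] <- v
      dbl_meta[[j]] <- cells[ab[1], ]
    }
    dbl <- dplyr::bind_rows(dbl_meta)
    dbl$cell_id <- sprintf("doublet_%03d", seq_len(cfg$n_doublets))
    dbl$planned_fail <- "doublet"
    dbl$is_doublet <- TRUE
    dbl$doublet_score <- stats::runif(cfg$n_doublets, 0.60, 0.95)
    colnames(dbl_cols) <- dbl$cell_id
    counts <- cbind(counts, dbl_cols)
    cells <- dplyr::bind_rows(cells, dbl)
  }

  m <- cell_matrix(
    counts,
    cell_meta = cells[, c("cell_id", "cell_type", "stage", "group",
                          "pseudotime", "doublet_score")],
    gene_meta = tibble::tibble(gene_id = ann$gene_id,
                               gene_name = ann$gene_name)
  )
  truth_genes <- tibble::tibble(
    gene_id = genes, biotype = biotype, mito = is_mito,
    base_mean = as.numeric(base_mu), archetype = unname(archetype)
  )
  truth_genes <- dplyr::bind_cols(
    truth_genes,
    tibble::as_tibble(mug, .name_repair = ~ paste0("mean_", groups))
  )
  list(matrix = m,
       truth = list(genes = truth_genes, pairs = pairs, cells = cells))
}

# analytic two-state solution: du/dt = alpha - beta u, ds/dt = beta u - gamma s
kin_solution <- function(alpha, beta, gamma, u0, s0, t) {
  u <- alpha / beta + (u0 - alpha / beta) * exp(-beta * t)
  c1 <- beta * (u0 - alpha / beta) / (gamma - beta)
  s <- alpha / gamma + c1 * exp(-beta * t) +
    (s0 - alpha / gamma - c1) * exp(-gamma * t)
  list(u = u, s = s)
}

#' Simulate spliced/unspliced layers from two-state kinetics
#'
#' Each gene follows `du/dt = alpha - beta u`, `ds/dt = beta u - gamma s`
#' with a per-group phase: induction cells start at the origin with
#' `alpha` on, repression cells start at the steady state with `alpha`
#' off, steady cells sit on the steady-state point `(alpha/beta,
#' alpha/gamma)`. Counts add negative-binomial sampling noise unless
#' `cfg$noiseless`.
#'
#' @param cfg A [sim_config()].
#' @param sim_ann A [simulate_annotation()] result (genes to simulate).
#' @param cells Optional cell table from [simulate_pseudotime()]; the
#'   default regenerates it from `cfg`.
#' @return A list: `spliced` and `unspliced` (genes x cells sparse
#'   matrices), `truth` (tibble `gene_id`, `alpha`, `beta`, `gamma`),
#'   `phases` (tibble `group`, `phase`), `cells`.
#' @export
simulate_kinetics <- function(cfg, sim_ann, cells = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cells)) cells <- simulate_pseudotime(cfg)
  withr::with_seed(cfg$seed + 51L, {
    ann <- sim_ann$annotation
    genes <- ann$gene_id
    kn <- cfg$kinetics
    n_genes <- length(genes)
    n_cells <- nrow(cells)
    alpha <- stats::runif(n_genes, kn$alpha_range[1], kn$alpha_range[2])
    beta <- rep(kn$beta, n_genes)
    gamma <- rep(kn$gamma, n_genes)
    phase <- kn$phases[cells$group]
    t_cell <- numeric(n_cells)
    t_cell[phase == "induction"] <- stats::runif(
      sum(phase == "induction"), 0.1, 1.5)
    t_cell[phase == "repression"] <- stats::runif(
      sum(phase == "repression"), 4, 8)

    u_mean <- matrix(0, n_genes, n_cells)
    s_mean <- matrix(0, n_genes, n_cells)
    for (ph in unique(phase)) {
      idx <- which(phase == ph)
      tt <- t_cell[idx]
      for (gi in seq_len(n_genes)) {
        sol <- switch(ph,
          steady = list(u = rep(alpha[gi] / beta[gi], length(idx)),
                        s = rep(alpha[gi] / gamma[gi], length(idx))),
          induction = kin_solution(alpha[gi], beta[gi], gamma[gi],
                                   0, 0, tt),
          repression = kin_solution(0, beta[gi], gamma[gi],
                                    alpha[gi] / beta[gi],
                                    alpha[gi] / gamma[gi], tt)
        )
        u_mean[gi, idx] <- sol$u
        s_mean[gi, idx] <- sol$s
      }
    }
    # per-cell size factors: library-scale variation spreads cells along
    # the steady-state line, as in real data
    sf <- if (is.null(kn$size_factor_sd) || cfg$noiseless) {
      rep(1, n_cells)
    } else {
      stats::rlnorm(n_cells, 0, kn$size_factor_sd)
    }
    u_mean <- pmax(sweep(u_mean, 2, sf, `*`), 0)
    s_mean <- pmax(sweep(s_mean, 2, sf, `*`), 0)
    draw <- function(mu) {
      if (cfg$noiseless) {
        round(mu)
      } else {
        matrix(stats::rnbinom(length(mu), size = kn$nb_size,
                              mu = as.numeric(mu)),
               nrow(mu), ncol(mu))
      }
    }
    u <- draw(u_mean)
    s <- draw(s_mean)
    dimnames(u) <- dimnames(s) <- list(genes, cells$cell_id)
    to_sparse <- function(x) methods::as(methods::as(
      Matrix::Matrix(x, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
    list(
      spliced = to_sparse(s), unspliced = to_sparse(u),
      truth = tibble::tibble(gene_id = genes, alpha = alpha,
                             beta = beta, gamma = gamma),
      phases = tibble::tibble(group = names(kn$phases),
                              phase = unname(kn$phases)),
      cells = cells
    )
  })
}

#' Write a complete synthetic fixture to disk
#'
#' GTF annotation, MTX triplets for counts and the spliced/unspliced
#' layers, a cell-metadata TSV and truth tables, so the full pipeline
#' can run from files alone.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @return Invisibly, a list with the generated objects and `paths`.
#' @export
simulate_fixture <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim_ann <- simulate_annotation(cfg)
  sim_cnt <- simulate_counts(cfg, sim_ann)
  kin <- simulate_kinetics(cfg, sim_ann, cells = sim_cnt$truth$cells)
  gtf <- file.path(dir, "annotation.gtf")
  write_gtf(sim_ann$annotation, gtf)
  counts_dir <- file.path(dir, "counts")
  write_mtx_triplet(sim_cnt$matrix, counts_dir)
  m_kin <- cell_matrix(
    sim_cnt$matrix$counts,
    cell_meta = sim_cnt$matrix$cell_meta,
    gene_meta = sim_cnt$matrix$gene_meta,
    layers = list(spliced = kin$spliced, unspliced = kin$unspliced)
  )
  spliced_dir <- file.path(dir, "spliced")
  unspliced_dir <- file.path(dir, "unspliced")
  write_mtx_triplet(m_kin, spliced_dir, layer = "spliced")
  write_mtx_triplet(m_kin, unspliced_dir, layer = "unspliced")
  meta_path <- file.path(dir, "cell_meta.tsv")
  readr::write_tsv(sim_cnt$matrix$cell_meta, meta_path)
  readr::write_tsv(sim_cnt$truth$pairs,
                   file.path(dir, "truth_pairs.tsv"))
  readr::write_tsv(sim_cnt$truth$cells,
                   file.path(dir, "truth_cells.tsv"))
  readr::write_tsv(kin$truth, file.path(dir, "truth_kinetics.tsv"))
  invisible(list(
    annotation = sim_ann, counts = sim_cnt, kinetics = kin,
    paths = list(gtf = gtf, counts = counts_dir, spliced = spliced_dir,
                 unspliced = unspliced_dir, cell_meta = meta_path)
  ))
}
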