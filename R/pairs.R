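#' The six lncRNA-PCG genomic configurations
#'
#' Factor levels, in display order: antisense head-to-head (XH), antisense
#' tail-to-tail (XT), intronic antisense (XI), exonic overlapping (XO),
#' sense upstream (SU), sense downstream (SD).
#' @export
CONFIGURATIONS <- c("XH", "XT", "XI", "XO", "SU", "SD")

#' Discover proximal lncRNA-PCG pairs
#'
#' Finds every same-chromosome pair of a lncRNA and a protein-coding gene
#' whose spans lie within `window_bp` of each other (distance mode;
#' overlapping spans have gap 0), or, in fixed-window mode, whose TSSs
#' fall in the same fixed genomic bin of width `window_bp`. Each pair is
#' classified with [classify_configuration()].
#'
#' @param ann An `lnc_annotation` table.
#' @param window_bp Maximum span gap in bp (distance mode) or bin width
#'   (fixed-window mode). Default 5000.
#' @param mode `"distance"` (default) or `"fixed-window"`.
#' @return A tibble of class `pair_table` with columns `chrom`, `lnc_id`,
#'   `lnc_name`, `pcg_id`, `pcg_name`, `configuration` (factor over the
#'   six labels) and `gap_bp`; attributes `window_bp` and `mode`.
#' @export
find_proximal_pairs <- function(ann, window_bp = 5000,
                                mode = c("distance", "fixed-window")) {
  mode <- match.arg(mode)
  if (!is.numeric(window_bp) || length(window_bp) != 1 || window_bp <= 0) {
    stop("window_bp must be a single positive number")
  }
  lnc <- dplyr::filter(ann, .data$biotype == "lncRNA")
  pcg <- dplyr::filter(ann, .data$biotype == "protein_coding")
  if (!nrow(lnc) || !nrow(pcg)) {
    stop("annotation must contain at least one lncRNA and one protein_coding gene")
  }
  if (mode == "distance") {
    # interval join with slack, then exact gap filter (findOverlaps'
    # maxgap counts positions strictly between ranges, i.e. gap - 1)
    lev <- unique(c(lnc$chrom, pcg$chrom))
    lgr <- GenomicRanges::GRanges(
      factor(lnc$chrom, lev), IRanges::IRanges(lnc$start, lnc$end))
    pgr <- GenomicRanges::GRanges(
      factor(pcg$chrom, lev), IRanges::IRanges(pcg$start, pcg$end))
    hits <- GenomicRanges::findOverlaps(lgr, pgr, maxgap = window_bp)
    idx <- tibble::tibble(i = S4Vectors::queryHits(hits),
                          j = S4Vectors::subjectHits(hits))
  } else {
    bin_of <- function(g) (gene_tss(g$strand, g$start, g$end) - 1L) %/%
      as.integer(window_bp)
    idx <- dplyr::inner_join(
      tibble::tibble(i = seq_len(nrow(lnc)), chrom = lnc$chrom,
                     bin = bin_of(lnc)),
      tibble::tibble(j = seq_len(nrow(pcg)), chrom = pcg$chrom,
                     bin = bin_of(pcg)),
      by = c("chrom", "bin"), relationship = "many-to-many"
    )[, c("i", "j")]
  }
  gap <- pmax(0L, pmax(lnc$start[idx$i], pcg$start[idx$j]) -
                pmin(lnc$end[idx$i], pcg$end[idx$j]))
  keep <- if (mode == "distance") gap <= window_bp else rep(TRUE, nrow(idx))
  idx <- idx[keep, , drop = FALSE]
  out <- tibble::tibble(
    chrom = lnc$chrom[idx$i],
    lnc_id = lnc$gene_id[idx$i],
    lnc_name = lnc$gene_name[idx$i],
    pcg_id = pcg$gene_id[idx$j],
    pcg_name = pcg$gene_name[idx$j],
    configuration = purrr::map2_chr(idx$i, idx$j, function(i, j)
      classify_configuration(lnc[i, ], pcg[j, ])),
    gap_bp = as.integer(gap[keep])
  )
  if (!nrow(out)) {
    out <- tibble::tibble(chrom = character(), lnc_id = character(),
                          lnc_name = character(), pcg_id = character(),
                          pcg_name = character(),
                          configuration = character(),
                          gap_bp = integer())
  }
  out <- dplyr::arrange(out, .data$chrom, .data$lnc_id, .data$pcg_id)
  out$configuration <- factor(out$configuration, levels = CONFIGURATIONS)
  structure(out, window_bp = window_bp, mode = mode,
            class = c("pair_table", class(tibble::tibble())))
}

#' Classify the genomic configuration of one lncRNA-PCG pair
#'
#' Deterministic priority cascade. Antisense pairs (strands differ):
#' `XO` if any lncRNA exon overlaps any PCG exon by at least 1 bp, else
#' `XI` if the lncRNA span lies fully inside the PCG span, else `XH`
#' (divergent, head-to-head) when the two TSSs are the closer pair of
#' ends and `XT` (convergent, tail-to-tail) when the two TESs are, with
#' ties going to `XH`. Sense pairs: `SU` when the lncRNA TSS lies
#' upstream of the PCG TSS in transcriptional orientation, else `SD`.
#'
#' @param lnc,pcg Single-row gene tables (rows of an `lnc_annotation`),
#'   the lncRNA and the protein-coding gene.
#' @return One of `"XH"`, `"XT"`, `"XI"`, `"XO"`, `"SU"`, `"SD"`.
#' @export
classify_configuration <- function(lnc, pcg) {
  if (lnc$chrom != pcg$chrom) {
    stop("pair members on different chromosomes: ",
         lnc$gene_id, " / ", pcg$gene_id)
  }
  if (lnc$strand != pcg$strand) {
    lex <- lnc$exons[[1]]
    pex <- pcg$exons[[1]]
    hit <- FALSE
    for (i in seq_len(nrow(lex))) {
      if (any(lex[i, 1] <= pex[, 2] & pex[, 1] <= lex[i, 2])) {
        hit <- TRUE
        break
      }
    }
    if (hit) return("XO")
    if (lnc$start >= pcg$start && lnc$end <= pcg$end) return("XI")
    d_tss <- abs(gene_tss(lnc$strand, lnc$start, lnc$end) -
                   gene_tss(pcg$strand, pcg$start, pcg$end))
    d_tes <- abs(gene_tes(lnc$strand, lnc$start, lnc$end) -
                   gene_tes(pcg$strand, pcg$start, pcg$end))
    return(if (d_tss <= d_tes) "XH" else "XT")
  }
  lt <- gene_tss(lnc$strand, lnc$start, lnc$end)
  pt <- gene_tss(pcg$strand, pcg$start, pcg$end)
  upstream <- if (lnc$strand == "+") lt < pt else lt > pt
  if (upstream) "SU" else "SD"
}

#' Configuration frequency spectrum of a pair table
#'
#' @param pairs A `pair_table`.
#' @param expressed Optional character vector of gene ids; pairs are kept
#'   only when both members are present in it.
#' @return A tibble with columns `configuration` (all six labels) and
#'   `fraction`, summing to 1.
#' @export
configuration_frequencies <- function(pairs, expressed = NULL) {
  if (!is.null(expressed)) {
    pairs <- dplyr::filter(pairs, .data$lnc_id %in% expressed,
                           .data$pcg_id %in% expressed)
  }
  if (!nrow(pairs)) stop("no pairs left after filtering")
  cf <- factor(as.character(pairs$configuration), levels = CONFIGURATIONS)
  tab <- table(cf)
  tibble::tibble(
    configuration = factor(CONFIGURATIONS, levels = CONFIGURATIONS),
    n = as.integer(tab[CONFIGURATIONS]),
    fraction = as.numeric(tab[CONFIGURATIONS]) / nrow(pairs)
  )
}

#' Nearest protein-coding gene to a lncRNA
#'
#' Minimises the span gap among same-chromosome protein-coding genes.
#' Ties go to the gene with the smaller (5'-most) start, then the
#' lexicographically smaller `gene_id`.
#'
#' @param lnc A single-row gene table (the lncRNA).
#' @param ann An `lnc_annotation` table.
#' @param window_bp Maximum gap considered; `Inf` (default) searches the
#'   whole chromosome.
#' @return The `gene_id` of the nearest PCG, or `NA_character_` when no
#'   PCG lies within `window_bp` on the chromosome.
#' @export
nearest_pcg <- function(lnc, ann, window_bp = Inf) {
  p <- dplyr::filter(ann, .data$biotype == "protein_coding",
                     .data$chrom == lnc$chrom)
  if (!nrow(p)) return(NA_character_)
  gap <- pmax(0L, pmax(lnc$start, p$start) - pmin(lnc$end, p$end))
  p <- p[gap <= window_bp, ]
  gap <- gap[gap <= window_bp]
  if (!nrow(p)) return(NA_character_)
  ord <- order(gap, p$start, p$gene_id)
  p$gene_id[ord[1]]
}
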