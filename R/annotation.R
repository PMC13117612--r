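#' Read a GENCODE-style GTF into a gene-model table
#'
#' Parses `gene` and `exon` feature rows of a GTF file into one row per
#' gene. Coordinates are kept 1-based inclusive as in the GTF; exon
#' intervals are merged per gene, and genes without exon rows fall back to
#' a single exon spanning the gene. Biotypes other than `lncRNA` and
#' `protein_coding` are collapsed to `"other"`.
#'
#' @param path Path to a GTF file (optionally gzipped). Both the quoted
#'   GENCODE attribute dialect (`key "value";`) and the unquoted dialect
#'   (`key value;`) are accepted.
#' @param biotype_attribute Attribute carrying the gene biotype
#'   (default `"gene_type"`; e.g. Ensembl uses `"gene_biotype"`).
#' @return A tibble of class `lnc_annotation` with columns `gene_id`,
#'   `gene_name`, `chrom`, `strand`, `start`, `end`, `biotype` and a
#'   list-column `exons` of two-column integer matrices (`start`, `end`).
#'   Chromosome order of first appearance is kept in attribute
#'   `chrom_order`.
#' @export
read_gtf <- function(path, biotype_attribute = "gene_type") {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  validate_gtf_coords(path)
  gff <- suppressWarnings(rtracklayer::readGFF(
    path,
    filter = list(type = c("gene", "exon"))
  ))
  gff <- tibble::as_tibble(as.data.frame(gff, stringsAsFactors = FALSE))
  if (!nrow(gff)) stop("no gene or exon records in GTF: ", path)
  if (!"gene_id" %in% names(gff) || anyNA(gff$gene_id)) {
    stop("GTF records missing gene_id attribute: ", path)
  }
  gff$seqid <- as.character(gff$seqid)
  gff$strand <- as.character(gff$strand)
  bt <- if (biotype_attribute %in% names(gff)) {
    as.character(gff[[biotype_attribute]])
  } else {
    rep(NA_character_, nrow(gff))
  }
  gff$biotype <- dplyr::if_else(
    bt %in% c("lncRNA", "protein_coding"), bt, "other", missing = "other"
  )
  if (!"gene_name" %in% names(gff)) gff$gene_name <- gff$gene_id
  gff$gene_name <- dplyr::coalesce(as.character(gff$gene_name), gff$gene_id)

  genes <- dplyr::filter(gff, .data$type == "gene")
  exons <- dplyr::filter(gff, .data$type == "exon")
  if (!nrow(genes)) stop("no 'gene' feature rows in GTF: ", path)
  if (anyDuplicated(genes$gene_id)) {
    warning("duplicate gene_id rows in GTF; keeping union span and merged exons")
  }

  gene_tbl <- genes |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      gene_name = dplyr::first(.data$gene_name),
      chrom = dplyr::first(.data$seqid),
      strand = dplyr::first(.data$strand),
      start = min(.data$start),
      end = max(.data$end),
      biotype = dplyr::first(.data$biotype),
      .groups = "drop"
    )
  if (!all(gene_tbl$strand %in% c("+", "-"))) {
    bad <- gene_tbl$gene_id[!gene_tbl$strand %in% c("+", "-")]
    stop("gene(s) without '+'/'-' strand: ", paste(bad, collapse = ", "))
  }

  exon_list <- split(
    Map(c, exons$start, exons$end),
    factor(exons$gene_id, levels = gene_tbl$gene_id)
  )
  gene_tbl$exons <- purrr::pmap(
    list(exon_list[gene_tbl$gene_id], gene_tbl$start, gene_tbl$end,
         gene_tbl$gene_id),
    function(ex, s, e, id) {
      if (is.null(ex) || !length(ex)) {
        return(matrix(c(s, e), ncol = 2,
                      dimnames = list(NULL, c("start", "end"))))
      }
      m <- do.call(rbind, ex)
      colnames(m) <- c("start", "end")
      m <- merge_intervals(m)
      if (any(m[, 1] < s) || any(m[, 2] > e)) {
        stop("exon outside gene span for gene: ", id)
      }
      m
    }
  )
  bad <- gene_tbl$start > gene_tbl$end
  if (any(bad)) {
    stop("gene span with start > end: ",
         paste(gene_tbl$gene_id[bad], collapse = ", "))
  }
  new_annotation(gene_tbl, chrom_order = unique(genes$seqid))
}

#' Write a gene-model table as GTF
#'
#' Emits one `gene` row and one `exon` row per exon, with `gene_id`,
#' `gene_name` and `gene_type` attributes in the quoted GENCODE dialect,
#' so that [read_gtf()] round-trips the annotation exactly.
#'
#' @param ann An `lnc_annotation` tibble from [read_gtf()] or
#'   [simulate_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "lnc_annotation"))
  ord <- order(match(ann$chrom, attr(ann, "chrom_order")), ann$start)
  ann <- ann[ord, ]
  lines <- purrr::pmap(
    list(ann$gene_id, ann$gene_name, ann$chrom, ann$strand,
         ann$start, ann$end, ann$biotype, ann$exons),
    function(id, nm, chr, str, s, e, bt, ex) {
      attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_type "%s";',
                       id, nm, bt)
      c(
        sprintf("%s\tlncpair\tgene\t%d\t%d\t.\t%s\t.\t%s",
                chr, s, e, str, attrs),
        sprintf("%s\tlncpair\texon\t%d\t%d\t.\t%s\t.\t%s",
                chr, ex[, 1], ex[, 2], str, attrs)
      )
    }
  )
  writeLines(unlist(lines), path)
  invisible(path)
}

new_annotation <- function(tbl, chrom_order = unique(tbl$chrom)) {
  tbl <- tibble::as_tibble(tbl)
  stopifnot(all(c("gene_id", "gene_name", "chrom", "strand", "start",
                  "end", "biotype", "exons") %in% names(tbl)))
  tbl$start <- as.integer(tbl$start)
  tbl$end <- as.integer(tbl$end)
  structure(tbl,
            chrom_order = chrom_order,
            class = c("lnc_annotation", class(tibble::tibble())))
}

# Coordinate columns 4 and 5 must be positive integers; errors name the
# offending (1-based, comment-inclusive) line so users can fix the file.
validate_gtf_coords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) stop("GTF has no feature lines: ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8)) {
    stop("malformed GTF record (fewer than 8 fields) at line ",
         idx[which(nf < 8)[1]])
  }
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  bad <- is.na(starts) | is.na(ends) | starts < 1L
  if (any(bad)) {
    stop("malformed coordinate field at line ", idx[which(bad)[1]])
  }
  invisible(TRUE)
}

# Merge overlapping/bookended 1-based inclusive intervals; rows sorted.
merge_intervals <- function(m) {
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  if (nrow(m) < 2) return(m)
  out <- list(m[1, ])
  for (i in seq(2, nrow(m))) {
    last <- out[[length(out)]]
    if (m[i, 1] <= last[2] + 1L) {
      out[[length(out)]] <- c(last[1], max(last[2], m[i, 2]))
    } else {
      out[[length(out) + 1]] <- m[i, ]
    }
  }
  res <- do.call(rbind, out)
  colnames(res) <- c("start", "end")
  res
}

#' Transcription start site of a gene span
#'
#' The TSS is the span start on the `+` strand and the span end on the
#' `-` strand; [gene_tes()] is the opposite end.
#'
#' @param strand `"+"` or `"-"` (vectorised).
#' @param start,end 1-based inclusive span coordinates.
#' @return Integer vector of TSS (or TES) positions.
#' @export
gene_tss <- function(strand, start, end) {
  as.integer(ifelse(strand == "+", start, end))
}

#' @rdname gene_tss
#' @export
gene_tes <- function(strand, start, end) {
  as.integer(ifelse(strand == "+", end, start))
}
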