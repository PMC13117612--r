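#' Construct a genes x cells count container
#'
#' Thin S3 container around a sparse count matrix with per-cell metadata
#' and optional spliced/unspliced layers of identical shape.
#'
#' @param counts genes x cells matrix of non-negative integer counts
#'   (coerced to `Matrix::dgCMatrix`); must carry row and column names.
#' @param cell_meta Tibble with a `cell_id` column matching the matrix
#'   columns; typical columns are `cell_type`, `stage`, `pseudotime`,
#'   `doublet_score`. Defaults to the bare `cell_id` table.
#' @param gene_meta Optional tibble with `gene_id` (matching rows) plus
#'   e.g. `gene_name`; defaults to `gene_id`/`gene_name` from row names.
#' @param layers Optional named list of matrices (e.g. `spliced`,
#'   `unspliced`) with the same dimnames as `counts`.
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cell_meta = NULL, gene_meta = NULL,
                        layers = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0) stop("counts must have gene (row) names")
    rownames(counts) <- character(0)
  }
  if (is.null(colnames(counts))) {
    if (ncol(counts) > 0) stop("counts must have cell (column) names")
    colnames(counts) <- character(0)
  }
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (is.null(cell_meta)) {
    cell_meta <- tibble::tibble(cell_id = colnames(counts))
  }
  cell_meta <- tibble::as_tibble(cell_meta)
  cells_ok <- identical(cell_meta$cell_id, colnames(counts)) ||
    (ncol(counts) == 0 && nrow(cell_meta) == 0)
  if (!"cell_id" %in% names(cell_meta) || !cells_ok) {
    stop("cell_meta$cell_id must match counts column names in order")
  }
  if (is.null(gene_meta)) {
    gene_meta <- tibble::tibble(gene_id = rownames(counts),
                                gene_name = rownames(counts))
  }
  gene_meta <- tibble::as_tibble(gene_meta)
  if (!identical(gene_meta$gene_id, rownames(counts)) &&
      !(nrow(counts) == 0 && nrow(gene_meta) == 0)) {
    stop("gene_meta$gene_id must match counts row names in order")
  }
  if (!is.null(layers)) {
    for (nm in names(layers)) {
      l <- layers[[nm]]
      if (!identical(dim(l), dim(counts))) {
        stop("layer '", nm, "' shape differs from counts")
      }
      layers[[nm]] <- methods::as(methods::as(
        Matrix::Matrix(l, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
      dimnames(layers[[nm]]) <- dimnames(counts)
    }
  }
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta, layers = layers),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("<cell_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells", sep = "")
  if (!is.null(x$layers)) {
    cat("; layers:", paste(names(x$layers), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Read a MatrixMarket triplet directory
#'
#' Reads the Cell Ranger convention: `matrix.mtx`, `features.tsv`,
#' `barcodes.tsv` (each optionally gzipped). Features files with two or
#' three columns (id, name, type) are accepted.
#'
#' @param dir Directory containing the three files.
#' @param cell_meta Optional tibble (or TSV path) of per-cell metadata
#'   with a `cell_id` column; reordered to the barcode order.
#' @return A [cell_matrix()].
#' @export
read_mtx_triplet <- function(dir, cell_meta = NULL) {
  find1 <- function(base) {
    for (f in file.path(dir, c(base, paste0(base, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    stop("missing ", base, "(.gz) in ", dir)
  }
  mtx_path <- find1("matrix.mtx")
  feat_path <- find1("features.tsv")
  bc_path <- find1("barcodes.tsv")
  m <- read_mm(mtx_path)
  feats <- readr::read_tsv(feat_path, col_names = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  bcs <- readr::read_tsv(bc_path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(feats) != nrow(m)) {
    stop("features.tsv has ", nrow(feats), " rows but matrix.mtx has ",
         nrow(m), " (file: ", feat_path, ")")
  }
  if (nrow(bcs) != ncol(m)) {
    stop("barcodes.tsv has ", nrow(bcs), " rows but matrix.mtx has ",
         ncol(m), " columns (file: ", bc_path, ")")
  }
  gene_meta <- tibble::tibble(
    gene_id = feats[[1]],
    gene_name = if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  )
  dimnames(m) <- list(gene_meta$gene_id, bcs[[1]])
  if (!is.null(cell_meta)) {
    if (is.character(cell_meta) && length(cell_meta) == 1) {
      cell_meta <- read_cell_meta(cell_meta)
    }
    cell_meta <- tibble::as_tibble(cell_meta)
    miss <- setdiff(colnames(m), cell_meta$cell_id)
    if (length(miss)) {
      stop("cell metadata missing barcodes: ",
           paste(utils::head(miss, 3), collapse = ", "))
    }
    cell_meta <- cell_meta[match(colnames(m), cell_meta$cell_id), ]
  }
  cell_matrix(m, cell_meta = cell_meta, gene_meta = gene_meta)
}

read_mm <- function(path) {
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile(fileext = ".mtx")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(readLines(gzfile(path)), tmp)
    path <- tmp
  }
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) stop("corrupt MatrixMarket file ",
                                         path, ": ", conditionMessage(e)))
  methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
}

#' Write a [cell_matrix()] as a MatrixMarket triplet directory
#'
#' @param m A `cell_matrix`.
#' @param dir Output directory (created if needed).
#' @param gzip Gzip the three files (default `FALSE`).
#' @param layer Which matrix to write: `"counts"` or a layer name.
#' @return `dir`, invisibly.
#' @export
write_mtx_triplet <- function(m, dir, gzip = FALSE, layer = "counts") {
  stopifnot(inherits(m, "cell_matrix"))
  mat <- if (layer == "counts") m$counts else m$layers[[layer]]
  if (is.null(mat)) stop("no such layer: ", layer)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  mtx_plain <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(mat, mtx_plain)
  if (gzip) {
    lines <- readLines(mtx_plain)
    con <- gzfile(file.path(dir, "matrix.mtx.gz"), "w")
    writeLines(lines, con)
    close(con)
    unlink(mtx_plain)
  }
  feat <- m$gene_meta
  feat$type <- "Gene Expression"
  writer <- function(x, base) {
    path <- file.path(dir, paste0(base, ext))
    con <- if (gzip) gzfile(path, "w") else file(path, "w")
    utils::write.table(x, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  writer(feat, "features.tsv")
  writer(m$cell_meta["cell_id"], "barcodes.tsv")
  invisible(dir)
}

#' Read a cell-metadata TSV
#'
#' Expected columns: `cell_id`, `cell_type`, `stage`, and optionally
#' `pseudotime` and `doublet_score`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_cell_meta <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    cell_id = "c", .default = readr::col_guess()
  ), comment = "#", progress = FALSE)
}

#' Per-cell quality-control statistics
#'
#' @param m A [cell_matrix()].
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes
#'   (GENCODE convention `"MT-"`).
#' @return Tibble with `cell_id`, `total_umi`, `n_genes`, `mito_frac`
#'   (0 for an all-zero cell).
#' @export
compute_cell_qc <- function(m, mito_prefix = "MT-") {
  tot <- Matrix::colSums(m$counts)
  ngene <- Matrix::colSums(m$counts > 0)
  mito <- startsWith(m$gene_meta$gene_name, mito_prefix)
  mtot <- if (any(mito)) {
    Matrix::colSums(m$counts[mito, , drop = FALSE])
  } else {
    rep(0, ncol(m$counts))
  }
  tibble::tibble(
    cell_id = colnames(m$counts),
    total_umi = unname(as.numeric(tot)),
    n_genes = unname(as.integer(ngene)),
    mito_frac = unname(as.numeric(ifelse(tot > 0, mtot / tot, 0)))
  )
}

#' Quality-control thresholds
#'
#' Defaults are the snRNA-seq settings used throughout: cells are kept
#' with 3,500-50,000 UMIs (inclusive), 1,500-5,000 detected genes
#' (inclusive), mitochondrial fraction strictly below 5%, and doublet
#' score strictly below 0.5.
#'
#' @param umi_min,umi_max Inclusive total-UMI bounds.
#' @param genes_min,genes_max Inclusive detected-gene bounds.
#' @param mito_max_frac Exclusive upper bound on mitochondrial fraction.
#' @param doublet_threshold Exclusive upper bound on doublet score.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(umi_min = 3500, umi_max = 50000,
                          genes_min = 1500, genes_max = 5000,
                          mito_max_frac = 0.05, doublet_threshold = 0.5) {
  stopifnot(umi_min <= umi_max, genes_min <= genes_max,
            mito_max_frac >= 0, mito_max_frac <= 1,
            doublet_threshold >= 0, doublet_threshold <= 1)
  structure(list(umi_min = umi_min, umi_max = umi_max,
                 genes_min = genes_min, genes_max = genes_max,
                 mito_max_frac = mito_max_frac,
                 doublet_threshold = doublet_threshold),
            class = "qc_thresholds")
}

#' Apply cell quality control
#'
#' Keeps a cell iff `umi_min <= total_umi <= umi_max`, `genes_min <=
#' n_genes <= genes_max`, `mito_frac < mito_max_frac` and (when a
#' `doublet_score` column is present) `doublet_score <
#' doublet_threshold`. A removed cell is attributed to the first failing
#' rule in that order.
#'
#' @param m A [cell_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @param mito_prefix Mitochondrial gene-name prefix.
#' @return A list: `matrix` (filtered `cell_matrix`), `cell_qc` (per-cell
#'   stats with `keep` and `fail_rule`), and `removed` (per-rule counts).
#' @export
apply_qc <- function(m, thresholds = qc_thresholds(),
                     mito_prefix = "MT-") {
  t <- thresholds
  qc <- compute_cell_qc(m, mito_prefix)
  if ("doublet_score" %in% names(m$cell_meta)) {
    qc$doublet_score <- m$cell_meta$doublet_score
  }
  rules <- list(
    umi_min = qc$total_umi < t$umi_min,
    umi_max = qc$total_umi > t$umi_max,
    genes_min = qc$n_genes < t$genes_min,
    genes_max = qc$n_genes > t$genes_max,
    mito = qc$mito_frac >= t$mito_max_frac
  )
  if ("doublet_score" %in% names(qc)) {
    rules$doublet <- qc$doublet_score >= t$doublet_threshold
  }
  fail <- rep(NA_character_, nrow(qc))
  for (nm in rev(names(rules))) fail[rules[[nm]]] <- nm
  qc$keep <- is.na(fail)
  qc$fail_rule <- fail
  removed <- tibble::tibble(
    rule = names(rules),
    n_removed = vapply(names(rules),
                       function(nm) sum(fail == nm, na.rm = TRUE),
                       integer(1))
  )
  keep_idx <- which(qc$keep)
  filtered <- cell_matrix(
    m$counts[, keep_idx, drop = FALSE],
    cell_meta = m$cell_meta[keep_idx, ],
    gene_meta = m$gene_meta,
    layers = if (!is.null(m$layers)) {
      lapply(m$layers, function(l) l[, keep_idx, drop = FALSE])
    }
  )
  list(matrix = filtered, cell_qc = qc, removed = removed)
}

#' Log counts-per-10k normalisation
#'
#' `ln(1 + count * scale / cell_total)` per entry. Zero-total cells are
#' returned as zero columns with a warning. The zero pattern is
#' preserved, so the result stays sparse.
#'
#' @param m A [cell_matrix()] or a genes x cells matrix.
#' @param scale Library-size target (default 1e4).
#' @return A sparse genes x cells matrix of normalised values.
#' @export
normalize_log <- function(m, scale = 1e4) {
  mat <- if (inherits(m, "cell_matrix")) m$counts else
    methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                            "generalMatrix"), "CsparseMatrix")
  tot <- Matrix::colSums(mat)
  if (any(tot == 0)) warning("all-zero cell(s) returned as zero columns")
  sf <- ifelse(tot > 0, scale / tot, 0)
  out <- mat %*% Matrix::Diagonal(x = sf)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(mat)
  methods::as(out, "CsparseMatrix")
}

#' Biotype accounting of a count matrix
#'
#' UMI share and mean per-cell detection per biotype (`lncRNA`,
#' `protein_coding`, `other`; gene ids missing from the annotation count
#' as `other`).
#'
#' @param m A [cell_matrix()].
#' @param ann An `lnc_annotation` table.
#' @return Tibble with `biotype`, `umi_fraction` (sums to 1),
#'   `mean_genes_per_cell` (mean detected genes of that biotype) and
#'   `mean_umi_per_cell`.
#' @export
biotype_fraction <- function(m, ann) {
  bt <- ann$biotype[match(rownames(m$counts), ann$gene_id)]
  bt[is.na(bt)] <- "other"
  lv <- c("lncRNA", "protein_coding", "other")
  total <- sum(m$counts)
  purrr::map_dfr(lv, function(b) {
    rows <- which(bt == b)
    sub <- m$counts[rows, , drop = FALSE]
    tibble::tibble(
      biotype = b,
      n_genes = length(rows),
      umi_fraction = if (total > 0) sum(sub) / total else 0,
      mean_genes_per_cell = mean(Matrix::colSums(sub > 0)),
      mean_umi_per_cell = mean(Matrix::colSums(sub))
    )
  })
}
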