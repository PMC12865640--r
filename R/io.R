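#' Read and validate a per-cell metadata table
#'
#' Reads a CSV/TSV of per-cell records into the validated layout the rest
#' of the package consumes: one row per cell with global micrometer
#' coordinates, a field-of-view id and a cell-type label.
#'
#' @param path CSV or TSV file with columns `cell_id`, `x_um`, `y_um`,
#'   `fov_id`, `cell_type`, and optionally `niche_id` and `region`
#'   (`"tumor"` / `"non_tumor"`).
#' @param drop_tumor If `TRUE` and a `region` column is present, rows with
#'   `region == "tumor"` are dropped, restricting downstream analyses to
#'   non-tumor tissue.
#' @return A tibble of validated cells.
#' @export
read_cells <- function(path, drop_tumor = FALSE) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  validate_cells(df, drop_tumor = drop_tumor)
}

#' Validate an in-memory cell table
#'
#' @param cells Data frame in the [read_cells()] layout.
#' @inheritParams read_cells
#' @return A validated tibble.
#' @export
validate_cells <- function(cells, drop_tumor = FALSE) {
  required <- c("cell_id", "x_um", "y_um", "fov_id", "cell_type")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0)
    stop("cell table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cells <- tibble::as_tibble(cells)
  cells$cell_id <- as.character(cells$cell_id)
  dups <- unique(cells$cell_id[duplicated(cells$cell_id)])
  if (length(dups) > 0)
    stop("duplicated cell_id(s): ",
         paste(utils::head(dups, 5), collapse = ", "), call. = FALSE)
  for (col in c("x_um", "y_um")) {
    v <- cells[[col]]
    if (!is.numeric(v))
      stop("column '", col, "' is not numeric", call. = FALSE)
    if (any(!is.finite(v)))
      stop("column '", col, "' contains non-finite values", call. = FALSE)
  }
  if (any(is.na(cells$cell_type)) || any(cells$cell_type == ""))
    stop("every cell must have a cell_type", call. = FALSE)
  if (drop_tumor && "region" %in% names(cells)) {
    n0 <- nrow(cells)
    cells <- dplyr::filter(cells, .data$region != "tumor")
    if (nrow(cells) < n0)
      message("dropped ", n0 - nrow(cells), " tumor-region cell(s)")
  }
  cells
}

#' Read a cells-by-genes expression matrix and align it to a cell table
#'
#' Supports MatrixMarket sparse triplets (CellRanger dialect: stored
#' genes x cells on disk with `genes.tsv`/`features.tsv` and
#' `barcodes.tsv` sidecars, transposed on read) and dense CSV (cells in
#' rows, first column `cell_id`). Rows are aligned to `cells$cell_id` by
#' id, never by file order.
#'
#' @param path Path to the `.mtx` file or the dense `.csv`.
#' @param cells Validated cell table whose row order defines the output
#'   row order.
#' @return A sparse `dgCMatrix`, cells x genes, rows in `cells` order.
#' @export
read_expression <- function(path, cells) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    dir <- dirname(path)
    gene_file <- c(file.path(dir, "genes.tsv"), file.path(dir, "features.tsv"))
    gene_file <- gene_file[file.exists(gene_file)][1]
    bc_file <- file.path(dir, "barcodes.tsv")
    if (is.na(gene_file) || !file.exists(bc_file))
      stop("MTX sidecar files (genes.tsv/features.tsv, barcodes.tsv) not found in ",
           dir, call. = FALSE)
    m <- methods::as(Matrix::readMM(path), "generalMatrix")
    genes <- readr::read_tsv(gene_file, col_names = FALSE,
                             show_col_types = FALSE, progress = FALSE)[[1]]
    barcodes <- readr::read_tsv(bc_file, col_names = FALSE,
                                show_col_types = FALSE, progress = FALSE)[[1]]
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
      stop("MTX dimensions do not match sidecar files", call. = FALSE)
    m <- Matrix::t(m)                     # to cells x genes
    dimnames(m) <- list(barcodes, genes)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
    m <- Matrix::Matrix(m, sparse = TRUE)
  }
  align_expression(m, cells)
}

#' Align an expression matrix to a cell table by cell id
#'
#' @param expr Matrix with `cell_id` rownames.
#' @param cells Validated cell table.
#' @return The matrix reordered to `cells$cell_id`, as `dgCMatrix`.
#' @export
align_expression <- function(expr, cells) {
  if (is.null(rownames(expr)))
    stop("expression matrix has no cell_id rownames to align by", call. = FALSE)
  missing_ids <- setdiff(cells$cell_id, rownames(expr))
  if (length(missing_ids) > 0)
    stop("cell_id(s) in cell table but not in expression matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  m <- expr[match(cells$cell_id, rownames(expr)), , drop = FALSE]
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

#' Write an expression matrix as MatrixMarket MTX with sidecars
#'
#' Stored genes x cells on disk (CellRanger dialect) with `genes.tsv` and
#' `barcodes.tsv` in the same directory.
#'
#' @param expr cells x genes matrix with dimnames.
#' @param path Output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_expression_mtx <- function(expr, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- Matrix::t(Matrix::Matrix(expr, sparse = TRUE))
  Matrix::writeMM(m, path)
  readr::write_tsv(tibble::tibble(gene = colnames(expr)),
                   file.path(dir, "genes.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(barcode = rownames(expr)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  invisible(path)
}

#' Read a one-to-one ligand-receptor pair table
#'
#' @param path TSV with columns `ligand` and `receptor`; a `pair_id`
#'   column is added as `ligand_receptor` when absent.
#' @return A tibble with `ligand`, `receptor`, `pair_id`.
#' @export
read_lr_pairs <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("ligand", "receptor"), names(df))
  if (length(missing_cols) > 0)
    stop("LR pair table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"pair_id" %in% names(df))
    df$pair_id <- paste(df$ligand, df$receptor, sep = "_")
  if (anyDuplicated(df$pair_id))
    stop("pair_id values must be unique", call. = FALSE)
  tibble::as_tibble(df[, c("ligand", "receptor", "pair_id")])
}

#' Restrict a ligand-receptor table to pairs measurable on a gene panel
#'
#' Keeps exactly the pairs whose ligand and receptor genes are both on the
#' panel, preserving input order — the standard step of intersecting a
#' curated interaction database with an imaging panel.
#'
#' @param pairs Tibble with `ligand`, `receptor` (and any other columns).
#' @param panel_genes Character vector of measured gene names.
#' @return The filtered tibble; empty results are allowed (with a message).
#' @examples
#' pairs <- tibble::tibble(ligand = c("IL1B", "TNF"),
#'                         receptor = c("IL1R1", "TNFRSF1A"),
#'                         pair_id = c("IL1B_IL1R1", "TNF_TNFRSF1A"))
#' filter_lr_pairs(pairs, c("IL1B", "IL1R1", "TNF"))
#' @export
filter_lr_pairs <- function(pairs, panel_genes) {
  out <- dplyr::filter(tibble::as_tibble(pairs),
                       .data$ligand %in% panel_genes,
                       .data$receptor %in% panel_genes)
  if (nrow(out) == 0)
    message("no LR pairs remain after panel filtering")
  out
}

#' Write a generated dataset to a directory of standard files
#'
#' `cells.csv`, `matrix.mtx` (+ sidecars), `lr_pairs.tsv`,
#' `ground_truth.json`.
#'
#' @param sim A `spax_sim` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "spax_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(sim$cells, file.path(dir, "cells.csv"))
  write_expression_mtx(sim$expr, file.path(dir, "matrix.mtx"))
  readr::write_tsv(sim$lr_pairs, file.path(dir, "lr_pairs.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
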