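#' Read a normalized expression matrix
#'
#' Reads a delimited (TSV/CSV, optionally gzipped) expression table into a
#' samples x genes numeric matrix. Values are assumed already normalized and
#' log-transformed; no normalization is applied here.
#'
#' @param path Input file. `.csv`/`.csv.gz` are comma-separated, anything else
#'   tab-separated.
#' @param genes_as Orientation on disk: `"rows"` (default; first column gene
#'   ids, remaining columns samples) or `"cols"` (first column sample ids).
#' @return A numeric matrix, samples in rows, genes in columns, with unique
#'   dimnames.
#' @export
read_expression_matrix <- function(path, genes_as = c("rows", "cols")) {
  genes_as <- match.arg(genes_as)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (genes_as == "rows") mat <- t(mat)
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat))) {
    stop("duplicate sample or gene ids in ", path, call. = FALSE)
  }
  if (any(!is.finite(mat))) {
    stop("non-finite values in expression matrix ", path, call. = FALSE)
  }
  mat
}

#' Write an expression matrix
#'
#' @param mat Samples x genes numeric matrix with dimnames.
#' @param path Output path (`.csv` writes comma-separated, else tab).
#' @param genes_as Orientation on disk; see [read_expression_matrix()].
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, genes_as = c("rows", "cols")) {
  genes_as <- match.arg(genes_as)
  out <- if (genes_as == "rows") t(mat) else mat
  id_col <- if (genes_as == "rows") "gene_id" else "sample_id"
  df <- tibble::as_tibble(out, rownames = id_col)
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Construct a single-cell cohort
#'
#' Bundles a cells x genes log-normalized expression matrix with per-cell
#' annotations (patient/tumor of origin, cell type, malignant flag).
#'
#' @param values Cells x genes numeric matrix (dense or `Matrix` sparse) with
#'   cell ids as rownames and gene ids as colnames.
#' @param annotations Data frame with columns `cell_id`, `tumor_name`,
#'   `cell_type`, `is_malignant`, one row per cell of `values`.
#' @return An object of class `cell_cohort`.
#' @export
cell_cohort <- function(values, annotations) {
  annotations <- tibble::as_tibble(annotations)
  req <- c("cell_id", "tumor_name", "cell_type", "is_malignant")
  miss <- setdiff(req, names(annotations))
  if (length(miss)) {
    stop("annotations missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have cell ids as rownames and gene ids as colnames",
         call. = FALSE)
  }
  if (nrow(values) != nrow(annotations) ||
      !all(rownames(values) == annotations$cell_id)) {
    stop("annotations must match the rows of `values` (same cells, same order)",
         call. = FALSE)
  }
  if (any(!nzchar(annotations$tumor_name)) || anyNA(annotations$tumor_name)) {
    stop("every cell needs a non-empty tumor_name", call. = FALSE)
  }
  if (!is.logical(annotations$is_malignant) || anyNA(annotations$is_malignant)) {
    stop("is_malignant must be logical with no missing values", call. = FALSE)
  }
  if (inherits(values, "Matrix")) {
    vals <- values
    if (any(!is.finite(vals@x))) stop("non-finite expression values",
                                      call. = FALSE)
  } else {
    storage.mode(values) <- "double"
    vals <- values
    if (any(!is.finite(vals))) stop("non-finite expression values",
                                    call. = FALSE)
  }
  structure(list(values = vals, cells = annotations), class = "cell_cohort")
}

#' @export
print.cell_cohort <- function(x, ...) {
  cat("<cell_cohort> ", nrow(x$values), " cells x ", ncol(x$values),
      " genes, ", length(unique(x$cells$tumor_name)), " tumors (",
      sum(x$cells$is_malignant), " malignant cells)\n", sep = "")
  invisible(x)
}

#' Subset a cell cohort
#'
#' @param cohort A [cell_cohort()].
#' @param cells Logical or character vector selecting cells, or
#' @param tumors Character vector of tumor names to keep (applied after
#'   `cells` if both given).
#' @return A [cell_cohort()] restricted to the selected cells.
#' @export
subset_cells <- function(cohort, cells = NULL, tumors = NULL) {
  keep <- rep(TRUE, nrow(cohort$values))
  if (!is.null(cells)) {
    keep <- if (is.logical(cells)) cells else cohort$cells$cell_id %in% cells
  }
  if (!is.null(tumors)) keep <- keep & cohort$cells$tumor_name %in% tumors
  cell_cohort(cohort$values[keep, , drop = FALSE],
              cohort$cells[keep, , drop = FALSE])
}

#' Read a single-cell cohort from disk
#'
#' Two on-disk layouts are supported: a dense TSV (cells in rows, first column
#' `cell_id`, genes in columns) or a 10x-style matrix-market triplet
#' (`.mtx` with genes in rows and cells in columns, plus one-column
#' `genes.tsv` / `barcodes.tsv` label files).
#'
#' @param matrix_path Path to the `.tsv` or `.mtx` expression file.
#' @param annotations_path TSV with columns `cell_id`, `tumor_name`,
#'   `cell_type`, `is_malignant`.
#' @param genes_path,barcodes_path Label files, required for `.mtx` input.
#' @return A [cell_cohort()].
#' @export
read_cell_cohort <- function(matrix_path, annotations_path,
                             genes_path = NULL, barcodes_path = NULL) {
  if (grepl("\\.mtx$", matrix_path)) {
    if (is.null(genes_path) || is.null(barcodes_path)) {
      stop("matrix-market input needs genes_path and barcodes_path",
           call. = FALSE)
    }
    m <- Matrix::readMM(matrix_path)
    genes <- readLines(genes_path, warn = FALSE)
    cells <- readLines(barcodes_path, warn = FALSE)
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop("matrix dimensions do not match label files", call. = FALSE)
    }
    dimnames(m) <- list(genes, cells)
    vals <- Matrix::t(m)
  } else {
    vals <- read_expression_matrix(matrix_path, genes_as = "cols")
  }
  ann <- read_cell_annotations(annotations_path)
  ann <- ann[match(rownames(vals), ann$cell_id), , drop = FALSE]
  cell_cohort(vals, ann)
}

#' Read per-cell annotations
#'
#' @param path TSV with columns `cell_id`, `tumor_name`, `cell_type`,
#'   `is_malignant` (logical or 0/1).
#' @return A tibble.
#' @export
read_cell_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.logical(ann$is_malignant)) {
    ann$is_malignant <- as.logical(as.integer(ann$is_malignant))
  }
  tibble::as_tibble(ann)
}

#' Write a single-cell cohort to disk
#'
#' Writes either a dense TSV (`format = "tsv"`) or a matrix-market triplet
#' (`format = "mtx"`: `matrix.mtx`, `genes.tsv`, `barcodes.tsv`), plus
#' `annotations.tsv`, into `dir`.
#'
#' @param cohort A [cell_cohort()].
#' @param dir Output directory, created if missing.
#' @param format `"tsv"` or `"mtx"`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_cell_cohort <- function(cohort, dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann_path <- file.path(dir, "annotations.tsv")
  readr::write_tsv(cohort$cells, ann_path, progress = FALSE)
  if (format == "tsv") {
    mat_path <- file.path(dir, "matrix.tsv")
    write_expression_matrix(as.matrix(cohort$values), mat_path,
                            genes_as = "cols")
    paths <- c(matrix = mat_path, annotations = ann_path)
  } else {
    mat_path <- file.path(dir, "matrix.mtx")
    m <- Matrix::Matrix(t(as.matrix(cohort$values)), sparse = TRUE)
    Matrix::writeMM(m, mat_path)
    writeLines(colnames(cohort$values), file.path(dir, "genes.tsv"))
    writeLines(rownames(cohort$values), file.path(dir, "barcodes.tsv"))
    paths <- c(matrix = mat_path, genes = file.path(dir, "genes.tsv"),
               barcodes = file.path(dir, "barcodes.tsv"),
               annotations = ann_path)
  }
  invisible(paths)
}

#' Read a subject response table
#'
#' @param path CSV with columns `subject_id`, `best_pct_change`,
#'   `confirmed_recist`, `confirmed_irrecist`, `benefit_months`,
#'   `new_therapy_within_1yr`, `evaluable`.
#' @return A tibble with logical flag columns.
#' @export
read_response_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("confirmed_recist", "confirmed_irrecist",
                "new_therapy_within_1yr", "evaluable")) {
    if (col %in% names(df) && !is.logical(df[[col]])) {
      df[[col]] <- as.logical(df[[col]])
    }
  }
  tibble::as_tibble(df)
}

#' Write a subject response table
#'
#' @param rows Data frame of subject responses.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(rows, path) {
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}
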