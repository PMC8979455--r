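#' Construct a cells x genes count matrix
#'
#' Light container for raw counts: a nonnegative integer matrix with unique
#' cell identifiers on rows and gene identifiers on columns. All pipeline
#' stages take this orientation (cells in rows).
#'
#' @param values numeric matrix of nonnegative integers, cells x genes.
#' @param cell_ids,gene_ids character vectors of unique identifiers matching
#'   the matrix dimensions; defaults are taken from `dimnames(values)` or
#'   generated.
#' @return An object of class `count_matrix` with elements `values`
#'   (dimnamed matrix), `cell_ids`, `gene_ids`.
#' @export
count_matrix <- function(values, cell_ids = NULL, gene_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- colnames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids); gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length (", length(cell_ids), ") != number of rows (",
         nrow(values), ")")
  if (length(gene_ids) != ncol(values))
    stop("gene_ids length (", length(gene_ids), ") != number of columns (",
         ncol(values), ")")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyNA(values) || any(values < 0))
    stop("counts must be nonnegative and non-missing")
  if (any(values != round(values)))
    stop("counts must be integers")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$values), "cells x", ncol(x$values), "genes\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

.norm_matrix <- function(values, cell_ids, gene_ids, provenance) {
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 provenance = provenance),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat("norm_matrix:", nrow(x$values), "cells x", ncol(x$values),
      "genes (log2 scale)\n")
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), unlist(lapply(
      x$provenance, paste, collapse = ",")), sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' @export
dim.norm_matrix <- function(x) dim(x$values)

#' Read a count matrix from disk
#'
#' Two on-disk layouts are supported: MatrixMarket triplets (`.mtx`) with
#' sidecar one-id-per-line files for rows and columns, and delimited text
#' (TSV/CSV) whose header row holds gene ids and whose first column holds
#' cell ids. 10X-style exports are genes x cells; pass `transpose = TRUE`
#' to flip them into the cells x genes orientation used here.
#'
#' @param path file to read.
#' @param format `"mtx"`, `"delimited"`, or `"auto"` (by file extension).
#' @param transpose if `TRUE` the source is genes x cells and is transposed.
#' @param cells_file,genes_file sidecar id files for MTX input, one id per
#'   line; defaults `<stem>_cells.txt` / `<stem>_genes.txt` next to `path`.
#'   They always name cells and genes respectively, whatever the stored
#'   orientation.
#' @param sep field separator for delimited input (`"auto"`: tab for
#'   .tsv/.txt, comma for .csv).
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = c("auto", "mtx", "delimited"),
                        transpose = FALSE,
                        cells_file = NULL, genes_file = NULL, sep = "auto") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (format == "auto")
    format <- if (ext == "mtx") "mtx" else "delimited"
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    if (is.null(cells_file)) cells_file <- paste0(stem, "_cells.txt")
    if (is.null(genes_file)) genes_file <- paste0(stem, "_genes.txt")
    if (!file.exists(cells_file)) stop("missing MTX sidecar file: ", cells_file)
    if (!file.exists(genes_file)) stop("missing MTX sidecar file: ", genes_file)
    m <- as.matrix(Matrix::readMM(path))
    if (transpose) m <- t(m)
    cell_ids <- readLines(cells_file)
    gene_ids <- readLines(genes_file)
    if (length(cell_ids) != nrow(m) || length(gene_ids) != ncol(m))
      stop("sidecar id counts (", length(cell_ids), " cells, ",
           length(gene_ids), " genes) do not match MTX dimensions ",
           nrow(m), " x ", ncol(m))
    count_matrix(m, cell_ids = cell_ids, gene_ids = gene_ids)
  } else {
    if (sep == "auto") sep <- if (ext == "csv") "," else "\t"
    tab <- tryCatch(
      read.delim(path, sep = sep, header = TRUE, row.names = 1,
                 check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("failed to parse ", path, ": ",
                               conditionMessage(e)))
    m <- as.matrix(tab)
    if (!is.numeric(m)) stop("non-numeric entries in ", path)
    if (transpose) m <- t(m)
    count_matrix(m)
  }
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]: `format = "mtx"` writes the triplet file plus
#' `<stem>_cells.txt` / `<stem>_genes.txt` sidecars; `format = "delimited"`
#' writes a TSV with gene-id header and cell-id first column.
#'
#' @param m a [count_matrix()].
#' @param path output file.
#' @param format `"mtx"` or `"delimited"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, format = c("delimited", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "count_matrix"))
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), path)
    writeLines(m$cell_ids, paste0(stem, "_cells.txt"))
    writeLines(m$gene_ids, paste0(stem, "_genes.txt"))
  } else {
    tab <- data.frame(cell_id = m$cell_ids, m$values, check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Quality-control filters on cells then genes
#'
#' Keeps cells expressing strictly more than `min_genes_per_cell` genes
#' (nonzero counts), then, on the retained cells, keeps genes whose count
#' exceeds `min_count` in at least a `min_cell_frac` fraction of cells.
#' "More than" and "greater than" are strict; "at least" is inclusive.
#' Cells are filtered before genes, so gene frequencies are computed on the
#' retained cells only. The filter is idempotent.
#'
#' @param m a [count_matrix()].
#' @param min_genes_per_cell keep cells with > this many detected genes
#'   (default 1000, calibrated for whole-transcriptome data; scale it down
#'   for small panels or simulations).
#' @param min_count gene expression threshold, strict (default 5).
#' @param min_cell_frac minimum fraction of retained cells exceeding
#'   `min_count`, inclusive (default 0.10).
#' @return A filtered [count_matrix()]; ids keep their original order.
#' @export
filter_cells_genes <- function(m, min_genes_per_cell = 1000,
                               min_count = 5, min_cell_frac = 0.10) {
  stopifnot(inherits(m, "count_matrix"))
  if (min_genes_per_cell < 0 || min_count < 0 || min_cell_frac < 0)
    stop("thresholds must be nonnegative")
  keep_cells <- rowSums(m$values > 0) > min_genes_per_cell
  if (!any(keep_cells))
    stop("empty after filtering: no cell has more than ", min_genes_per_cell,
         " detected genes")
  v <- m$values[keep_cells, , drop = FALSE]
  keep_genes <- colMeans(v > min_count) >= min_cell_frac
  if (!any(keep_genes))
    stop("empty after filtering: no gene exceeds count ", min_count,
         " in at least ", round(100 * min_cell_frac), "% of retained cells")
  count_matrix(v[, keep_genes, drop = FALSE],
               cell_ids = m$cell_ids[keep_cells],
               gene_ids = m$gene_ids[keep_genes])
}

#' Library-size scaling and log2 transform
#'
#' `method = "size_factor"` rescales every cell to the median library size of
#' the data, then applies `log2(x + 1)`; cells with identical relative
#' profiles become identical rows regardless of sequencing depth.
#' `method = "none"` applies only the log step, for matrices normalized
#' externally.
#'
#' @param m a [count_matrix()].
#' @param method `"size_factor"` (default) or `"none"`.
#' @return A `norm_matrix` (log2 scale, entries >= 0) carrying a
#'   `provenance` record of the transform.
#' @export
normalize_log <- function(m, method = c("size_factor", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "count_matrix"))
  if (nrow(m$values) == 0L || ncol(m$values) == 0L) stop("empty matrix")
  v <- m$values
  if (method == "size_factor") {
    lib <- rowSums(v)
    if (any(lib == 0))
      stop("cell(s) with zero total count: ",
           paste(head(m$cell_ids[lib == 0], 5), collapse = ", "))
    v <- v * (median(lib) / lib)
  }
  .norm_matrix(log2(v + 1), m$cell_ids, m$gene_ids,
               provenance = list(transform = "log2(1+x)", scaling = method))
}
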