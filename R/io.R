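#' Read a single-cell count matrix
#'
#' Accepts either a directory containing an MTX triplet (`matrix.mtx` with
#' genes in rows and cells in columns, plus `features.tsv` and
#' `barcodes.tsv`, one identifier per line) or a dense TSV with cells in
#' rows, a `cell` first column and genes as the remaining columns. Either
#' way the result is a cells x genes matrix.
#'
#' @param path directory (MTX triplet) or TSV file.
#' @return A cells x genes numeric matrix with dimnames.
#' @export
read_cell_counts <- function(path) {
  if (dir.exists(path)) {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    feats <- readLines(file.path(path, "features.tsv"))
    cells <- readLines(file.path(path, "barcodes.tsv"))
    m <- as.matrix(Matrix::t(m))
    dimnames(m) <- list(cells, feats)
    m
  } else {
    d <- readr::read_tsv(path, show_col_types = FALSE)
    m <- as.matrix(d[-1])
    rownames(m) <- d[[1]]
    m
  }
}

#' Write a single-cell count matrix as an MTX triplet
#'
#' @param counts cells x genes matrix.
#' @param dir output directory (created if needed); receives `matrix.mtx`
#'   (genes x cells, sparse), `features.tsv` and `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_cell_counts <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- Matrix::Matrix(t(as.matrix(counts)), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "features.tsv"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read / write cell group labels
#'
#' Two-column TSV (`cell`, `group`).
#'
#' @param path TSV file.
#' @return Named character vector mapping cell to group.
#' @export
read_cell_labels <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  setNames(as.character(d$group), d$cell)
}

#' @rdname read_cell_labels
#' @param labels named character vector.
#' @export
write_cell_labels <- function(labels, path) {
  readr::write_tsv(tibble(cell = names(labels), group = unname(labels)), path)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' Used for the housekeeping, transcription-factor and inflammation
#' annotation sets consumed by [filter_targets()].
#'
#' @param path text file, one gene symbol per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return Character vector of upper-cased symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0) return(character())
  normalize_symbols(x)
}
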