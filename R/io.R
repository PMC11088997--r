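#' Clone-table and count-matrix I/O
#'
#' Plain-text interchange: clone tables as TSV, count matrices as
#' MatrixMarket MTX with row (gene) and column (cell) TSVs, and truth /
#' QC summaries as JSON.
#'
#' @param clone_table data.frame (cell_id, clone_id, class, arm, batch).
#' @param path output file.
#' @name clonalfate-io
NULL

#' @rdname clonalfate-io
#' @export
write_clone_table <- function(clone_table, path) {
  write.table(clone_table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname clonalfate-io
#' @export
read_clone_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = "character")
}

#' @rdname clonalfate-io
#' @param counts genes x cells sparse matrix with dimnames.
#' @param dir output directory; writes \code{matrix.mtx}, \code{genes.tsv},
#'   \code{cells.tsv}.
#' @export
write_counts_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' @rdname clonalfate-io
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "cells.tsv")))
  methods::as(m, "CsparseMatrix")
}

#' @rdname clonalfate-io
#' @param x list to serialize.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
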