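#' Construct an expression matrix object
#'
#' The package-internal orientation is rows = genes, columns = cells,
#' matching how subgraph feature tensors are laid out downstream.
#'
#' @param values numeric matrix, genes in rows and cells in columns.
#' @param gene_ids,cell_ids unique identifiers; default to dimnames.
#' @param tf_ids character vector of transcription-factor gene ids (may
#'   include ids absent from the matrix; those are ignored with a message).
#' @return an `expression_matrix`: list with `values`, `gene_ids`,
#'   `cell_ids` and a per-gene logical `is_tf`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              tf_ids = character()) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene identifiers: ", paste(dups, collapse = ", "))
  }
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("expression values must be finite numerics")
  storage.mode(values) <- "double"
  dimnames(values) <- list(gene_ids, cell_ids)
  obj <- list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
              is_tf = gene_ids %in% as.character(tf_ids))
  class(obj) <- "expression_matrix"
  obj
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells (%d TFs)\n",
              length(x$gene_ids), length(x$cell_ids), sum(x$is_tf)))
  invisible(x)
}

#' Read an expression matrix
#'
#' Dense TSV/CSV files must have gene ids in the first column and one header
#' row of cell ids. MatrixMarket (`mtx`) input expects companion files with
#' gene and cell identifiers, one per line, in matrix order.
#'
#' @param path file path (for `format = "mtx"`, the `.mtx` file).
#' @param format `"tsv"`, `"csv"` or `"mtx"`; default guessed from the
#'   extension.
#' @param genes_path,cells_path identifier files for `mtx` input; default to
#'   `<path>.genes.txt` / `<path>.cells.txt` next to the matrix.
#' @param tf_ids optional TF identifiers to flag.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                            genes_path = NULL, cells_path = NULL,
                            tf_ids = character()) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx", "tsv")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    if (is.null(genes_path)) genes_path <- paste0(path, ".genes.txt")
    if (is.null(cells_path)) cells_path <- paste0(path, ".cells.txt")
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(genes_path)
    cell_ids <- readLines(cells_path)
    return(expression_matrix(m, gene_ids, cell_ids, tf_ids))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(df[[1L]])
  m <- df[, -1L, drop = FALSE]
  bad <- which(!vapply(m, is.numeric, logical(1)))
  if (length(bad)) {
    col <- bad[1L]
    row <- which(is.na(suppressWarnings(as.numeric(m[[col]]))))[1L]
    stop(sprintf("non-numeric expression value at row %s, column '%s'",
                 ifelse(is.na(row), "?", row), colnames(m)[col]))
  }
  expression_matrix(as.matrix(m), gene_ids, colnames(m), tf_ids)
}

#' Write an expression matrix
#'
#' @param expr an [expression_matrix()].
#' @param path output file; `.mtx` extension writes MatrixMarket plus
#'   `.genes.txt` / `.cells.txt` companions, otherwise a dense TSV/CSV.
#' @param format as in [read_expression()].
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path,
                             format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx", "tsv")
  }
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(expr$values, sparse = TRUE), path)
    writeLines(expr$gene_ids, paste0(path, ".genes.txt"))
    writeLines(expr$cell_ids, paste0(path, ".cells.txt"))
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(gene = expr$gene_ids, expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a directed edge list
#'
#' Two-column (regulator, target) TSV with an optional third numeric score
#' column and optional header. Self-loops are dropped with a message giving
#' the count.
#'
#' @param path TSV file path.
#' @return a data.frame with columns `regulator`, `target` and, when present
#'   in the file, `score`. Duplicate ordered pairs are collapsed.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  header <- grepl("regulator|source|tf", tolower(first))
  df <- utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("edge list must have at least two tab-separated columns")
  out <- data.frame(regulator = as.character(df[[1L]]),
                    target = as.character(df[[2L]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 3L && is.numeric(df[[3L]])) out$score <- df[[3L]]
  loops <- out$regulator == out$target
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped from ", path)
    out <- out[!loops, , drop = FALSE]
  }
  out <- out[!duplicated(out[c("regulator", "target")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a directed edge list as TSV
#'
#' @param edges data.frame with `regulator`, `target` and optional extra
#'   columns.
#' @param path output path.
#' @param header write a header row.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path, header = TRUE) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read a TF list (one gene identifier per line)
#'
#' @param path text file path.
#' @return character vector of unique identifiers.
#' @export
read_tf_list <- function(path) {
  ids <- trimws(readLines(path))
  unique(ids[nzchar(ids)])
}
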