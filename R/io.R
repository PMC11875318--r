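#' Read a count matrix from MTX triplet files
#'
#' Reads the MatrixMarket triplet file plus the features/barcodes sidecars
#' (one identifier per line, optionally extra tab-separated columns) and an
#' optional coordinates TSV. The MTX is expected gene-by-location
#' orientation is auto-detected from the sidecar lengths; a square matrix is
#' taken as location-by-gene.
#'
#' @param mtx path to the .mtx file.
#' @param features,barcodes paths to the gene / location id files.
#' @param coords path to a TSV with columns \code{x}, \code{y} (and
#'   optionally \code{location_id}); required to build a
#'   \code{spatial_counts}.
#' @return a [spatial_counts()] object.
#' @export
read_counts_mtx <- function(mtx, features, barcodes, coords) {
  M <- Matrix::readMM(mtx)
  genes <- utils::read.delim(features, header = FALSE,
                             stringsAsFactors = FALSE)[, 1]
  cells <- utils::read.delim(barcodes, header = FALSE,
                             stringsAsFactors = FALSE)[, 1]
  if (nrow(M) == length(genes) && ncol(M) == length(cells) &&
      length(genes) != length(cells))
    M <- Matrix::t(M)
  co <- utils::read.delim(coords, stringsAsFactors = FALSE)
  spatial_counts(methods::as(M, "CsparseMatrix"),
                 as.matrix(co[, c("x", "y")]),
                 gene_names = genes, location_ids = cells)
}

#' Write a spatial counts object as MTX + TSV sidecars
#'
#' Emits \code{matrix.mtx} (location-by-gene), \code{features.tsv},
#' \code{barcodes.tsv} and \code{coords.tsv} into \code{dir}; for a
#' \code{simulated_tissue} additionally \code{labels.tsv} with the
#' ground-truth domains.
#'
#' @param x a \code{spatial_counts} or \code{simulated_tissue}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- NULL
  if (inherits(x, "simulated_tissue")) {
    labels <- x$domain_labels
    x <- as_spatial_counts(x)
  }
  Matrix::writeMM(methods::as(Matrix::Matrix(x$counts, sparse = TRUE),
                              "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(x$gene_names, file.path(dir, "features.tsv"))
  writeLines(x$location_ids, file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(location_id = x$location_ids, x = x$coords[, 1],
               y = x$coords[, 2]),
    file.path(dir, "coords.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(labels))
    utils::write.table(
      data.frame(location_id = x$location_ids, domain = labels),
      file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  invisible(dir)
}

#' Read a count table from CSV/TSV
#'
#' First column is taken as the location id; remaining columns are genes.
#'
#' @param file path to a delimited count table (locations in rows).
#' @param coords path to a coordinates TSV with columns \code{x}, \code{y}.
#' @param sep field separator (default auto: tab for .tsv, comma otherwise).
#' @return a [spatial_counts()] object.
#' @export
read_counts_csv <- function(file, coords, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", file)) "\t" else ","
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(tab[, 1])
  M <- as.matrix(tab[, -1, drop = FALSE])
  co <- utils::read.delim(coords, stringsAsFactors = FALSE)
  spatial_counts(M, as.matrix(co[, c("x", "y")]),
                 gene_names = colnames(M), location_ids = ids)
}

#' Write the QC report produced by qc_filter
#'
#' @param filtered the result of [qc_filter()].
#' @param file output TSV path.
#' @export
write_qc_report <- function(filtered, file) {
  rep <- attr(filtered, "qc_report")
  if (is.null(rep)) stop("no qc_report attribute; run qc_filter first",
                         call. = FALSE)
  utils::write.table(rep, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

write_matrix_tsv <- function(M, file, ids = NULL) {
  df <- as.data.frame(as.matrix(M))
  if (!is.null(ids)) df <- cbind(location_id = ids, df)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
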