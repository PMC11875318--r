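#' Assemble a spatial counts object
#'
#' Bundles a location-by-gene count matrix with its spatial coordinates so the
#' two stay row-aligned through filtering. Counts may be dense or a
#' \code{Matrix} sparse matrix; they must be non-negative and integral.
#'
#' @param counts n x m matrix of raw counts (locations in rows, genes in
#'   columns); dense or \code{dgCMatrix}.
#' @param coords n x 2 numeric matrix of spatial coordinates in platform units
#'   (micrometres or array coordinates).
#' @param gene_names optional character vector of m gene identifiers; defaults
#'   to \code{colnames(counts)}.
#' @param location_ids optional character vector of n unique location
#'   identifiers; defaults to \code{rownames(counts)}.
#'
#' @return An object of class \code{spatial_counts}: a list with elements
#'   \code{counts}, \code{coords}, \code{gene_names}, \code{location_ids}.
#' @export
spatial_counts <- function(counts, coords, gene_names = NULL,
                           location_ids = NULL) {
  if (!inherits(counts, "Matrix")) counts <- as.matrix(counts)
  coords <- as.matrix(coords)
  if (nrow(counts) != nrow(coords))
    stop("counts and coords must have the same number of rows", call. = FALSE)
  if (ncol(coords) != 2L)
    stop("coords must have exactly two columns", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("coords must be finite", call. = FALSE)
  vals <- if (inherits(counts, "sparseMatrix")) counts@x else counts
  if (length(vals) && (min(vals) < 0 || any(vals != round(vals))))
    stop("counts must be non-negative integers", call. = FALSE)
  if (is.null(gene_names)) gene_names <- colnames(counts)
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(counts)))
  if (is.null(location_ids)) location_ids <- rownames(counts)
  if (is.null(location_ids))
    location_ids <- paste0("loc", seq_len(nrow(counts)))
  if (anyDuplicated(location_ids))
    stop("location_ids must be unique", call. = FALSE)
  structure(
    list(counts = counts, coords = coords,
         gene_names = as.character(gene_names),
         location_ids = as.character(location_ids)),
    class = "spatial_counts")
}

#' @export
print.spatial_counts <- function(x, ...) {
  cat("spatial_counts: ", nrow(x$counts), " locations x ",
      ncol(x$counts), " genes\n", sep = "")
  invisible(x)
}

#' @export
dim.spatial_counts <- function(x) dim(x$counts)

#' Quality-control filtering of spatial count data
#'
#' Removes low-quality locations using three intersective criteria on the raw
#' counts: (i) mitochondrial + ribosomal fraction of the library above
#' \code{mito_ribo_frac_max}; (ii) total counts below \code{min_reads};
#' (iii) total counts above \code{median + mad_multiplier * MAD} of the
#' per-location totals (upper-tail outlier trimming; the MAD is the raw median
#' absolute deviation, without the normal-consistency constant). Coordinates
#' are subset in lockstep.
#'
#' Mitochondrial/ribosomal genes are identified by name prefix. Panel-based
#' assays often carry none of these genes; an empty prefix list (or no
#' matching genes) simply disables that criterion.
#'
#' @param x a \code{spatial_counts} object.
#' @param mito_ribo_frac_max maximum allowed mito+ribo fraction (default 0.10).
#' @param min_reads minimum total counts per location (default 100).
#' @param mad_multiplier MAD multiplier for the upper-tail totals filter
#'   (default 5).
#' @param mito_prefixes,ribo_prefixes character vectors of gene-name prefixes
#'   (case sensitive); set to \code{character(0)} to skip the fraction filter.
#'
#' @return The filtered \code{spatial_counts}, with a \code{qc_report}
#'   attribute: a data.frame with one row per input location (id, total,
#'   mito+ribo fraction, per-criterion pass flags and the overall flag), and a
#'   \code{qc_removed} attribute counting removals per criterion.
#' @export
qc_filter <- function(x, mito_ribo_frac_max = 0.10, min_reads = 100,
                      mad_multiplier = 5,
                      mito_prefixes = c("mt-", "MT-", "Mt-"),
                      ribo_prefixes = c("Rps", "Rpl", "RPS", "RPL")) {
  stopifnot(inherits(x, "spatial_counts"))
  if (mito_ribo_frac_max < 0 || mito_ribo_frac_max > 1)
    stop("mito_ribo_frac_max must be in [0, 1]", call. = FALSE)
  if (min_reads < 0) stop("min_reads must be >= 0", call. = FALSE)
  if (mad_multiplier <= 0) stop("mad_multiplier must be > 0", call. = FALSE)

  totals <- as.numeric(Matrix::rowSums(x$counts))
  prefixes <- c(mito_prefixes, ribo_prefixes)
  if (length(prefixes)) {
    pat <- paste0("^(", paste(sapply(prefixes, function(p)
      gsub("([.|()\\^{}+$*?\\[\\]\\\\-])", "\\\\\\1", p)), collapse = "|"),
      ")")
    mr <- grepl(pat, x$gene_names)
  } else {
    mr <- rep(FALSE, length(x$gene_names))
  }
  mr_counts <- if (any(mr))
    as.numeric(Matrix::rowSums(x$counts[, mr, drop = FALSE]))
  else rep(0, length(totals))
  frac <- ifelse(totals > 0, mr_counts / totals, 0)

  med <- stats::median(totals)
  mad_raw <- stats::mad(totals, constant = 1)
  upper <- med + mad_multiplier * mad_raw

  pass_frac <- frac <= mito_ribo_frac_max
  pass_min <- totals >= min_reads
  pass_mad <- totals <= upper
  keep <- pass_frac & pass_min & pass_mad

  removed <- c(mito_ribo = sum(!pass_frac), min_reads = sum(!pass_min),
               mad_upper = sum(!pass_mad))
  if (!any(keep)) {
    worst <- names(removed)[which.max(removed)]
    stop("qc_filter removed every location; binding criterion: ", worst,
         call. = FALSE)
  }

  report <- data.frame(
    location_id = x$location_ids, total = totals, mito_ribo_frac = frac,
    pass_mito_ribo = pass_frac, pass_min_reads = pass_min,
    pass_mad = pass_mad, pass = keep, stringsAsFactors = FALSE)

  out <- spatial_counts(x$counts[keep, , drop = FALSE],
                        x$coords[keep, , drop = FALSE],
                        gene_names = x$gene_names,
                        location_ids = x$location_ids[keep])
  attr(out, "qc_report") <- report
  attr(out, "qc_removed") <- removed
  out
}

#' Library-size normalization and log transform
#'
#' Scales each location's counts to a common library size and optionally
#' applies \code{log1p}. Each row is divided by its total and multiplied by
#' \code{target_sum} (default: the median of the per-location totals), the
#' standard size-factor normalization for spatial and single-cell data. The
#' zero pattern is preserved exactly (\code{log1p(0) = 0}) and sparse input
#' stays sparse.
#'
#' @param x a \code{spatial_counts} object (typically after [qc_filter()]).
#' @param target_sum positive number, \code{"median"} for the median of
#'   per-location totals, or \code{NULL} to skip library-size scaling
#'   entirely (log transform only). Skipping is appropriate when differences
#'   in total counts are themselves biological signal, as in simulated
#'   tissues whose domains differ by a global expression fold change.
#' @param log1p apply \code{log(1 + x)} after scaling (default \code{TRUE}).
#' @param scale_genes z-score genes after normalization (off by default; the
#'   downstream PCA centers but does not scale).
#'
#' @return A \code{spatial_expr} object: list with \code{X} (n x m normalized
#'   matrix, sparse if the input was sparse and \code{scale_genes} is off),
#'   \code{coords}, \code{gene_names}, \code{location_ids},
#'   \code{target_sum}.
#' @export
normalize_counts <- function(x, target_sum = "median", log1p = TRUE,
                             scale_genes = FALSE) {
  stopifnot(inherits(x, "spatial_counts"))
  if (nrow(x$counts) == 0L) stop("no locations to normalize", call. = FALSE)
  totals <- as.numeric(Matrix::rowSums(x$counts))
  if (any(totals == 0))
    stop("locations with zero total counts; run qc_filter first",
         call. = FALSE)
  if (is.null(target_sum)) {
    ts <- NA_real_
    fac <- rep(1, length(totals))
  } else {
    ts <- if (identical(target_sum, "median")) stats::median(totals)
          else as.numeric(target_sum)
    if (!is.finite(ts) || ts <= 0)
      stop("target_sum must be positive", call. = FALSE)
    fac <- ts / totals
  }

  if (inherits(x$counts, "sparseMatrix")) {
    X <- Matrix::Diagonal(x = fac) %*% x$counts
    X <- methods::as(X, "CsparseMatrix")
    if (log1p) X@x <- log1p(X@x)
  } else {
    X <- x$counts * fac
    if (log1p) X <- log1p(X)
  }
  if (scale_genes) {
    X <- as.matrix(X)
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
  }
  rownames(X) <- x$location_ids
  colnames(X) <- x$gene_names
  structure(
    list(X = X, coords = x$coords, gene_names = x$gene_names,
         location_ids = x$location_ids, target_sum = ts),
    class = "spatial_expr")
}

#' @export
print.spatial_expr <- function(x, ...) {
  cat("spatial_expr: ", nrow(x$X), " locations x ", ncol(x$X),
      " genes (normalized)\n", sep = "")
  invisible(x)
}
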