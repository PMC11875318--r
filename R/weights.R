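#' k-nearest neighbours by exact search
#'
#' Exact brute-force kNN computed in row blocks so the full pairwise distance
#' matrix is never held in memory. Ties at the neighbourhood boundary are
#' broken by index order, so results are deterministic on gridded coordinates.
#'
#' @param coords n x d numeric matrix.
#' @param k number of neighbours to retain (1 <= k <= n-1); self excluded.
#' @param metric \code{"euclidean"} or \code{"manhattan"}.
#' @param block_size rows per block of the search.
#'
#' @return list with \code{idx} (n x k integer matrix of neighbour indices,
#'   nearest first) and \code{dist} (n x k distances).
#' @export
knn_neighbors <- function(coords, k, metric = c("euclidean", "manhattan"),
                          block_size = 1024L) {
  metric <- match.arg(metric)
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  n <- nrow(coords)
  if (n < 2L) stop("need at least two locations", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k >= n)
    stop("k must satisfy 1 <= k <= n - 1", call. = FALSE)

  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  sq <- rowSums(coords^2)
  for (start in seq(1L, n, by = block_size)) {
    rows <- start:min(start + block_size - 1L, n)
    if (metric == "euclidean") {
      d <- sq[rows] - 2 * tcrossprod(coords[rows, , drop = FALSE], coords)
      d <- sweep(d, 2L, sq, "+")
      d[d < 0] <- 0
    } else {
      d <- matrix(0, length(rows), n)
      for (j in seq_len(ncol(coords)))
        d <- d + abs(outer(coords[rows, j], coords[, j], "-"))
    }
    for (r in seq_along(rows)) {
      di <- d[r, ]
      di[rows[r]] <- Inf
      o <- order(di)[seq_len(k)]   # order() is stable: ties -> lowest index
      idx[rows[r], ] <- o
      dst[rows[r], ] <- di[o]
    }
  }
  if (metric == "euclidean") dst <- sqrt(dst)
  list(idx = idx, dist = dst)
}

#' Sparse kNN distance matrix
#'
#' Row i of the result holds the distances from location i to its
#' \code{threshold} nearest neighbours; all other pairs are structurally
#' absent. The matrix is generally asymmetric (kNN is not a symmetric
#' relation).
#'
#' @param coords n x 2 coordinate matrix.
#' @param threshold number of nearest neighbours retained per location.
#' @param metric distance metric, see [knn_neighbors()].
#' @param knn optional precomputed result of \code{knn_neighbors} with at
#'   least \code{threshold} columns (used by the sweep harness to avoid
#'   repeated searches).
#'
#' @return an n x n \code{dgCMatrix} of distances.
#' @export
knn_sparse_distances <- function(coords, threshold,
                                 metric = c("euclidean", "manhattan"),
                                 knn = NULL) {
  metric <- match.arg(metric)
  n <- nrow(as.matrix(coords))
  threshold <- as.integer(threshold)
  if (threshold >= n)
    stop("threshold must be smaller than the number of locations",
         call. = FALSE)
  if (is.null(knn)) {
    knn <- knn_neighbors(coords, threshold, metric)
  } else {
    if (ncol(knn$idx) < threshold)
      stop("precomputed knn has fewer than `threshold` neighbours",
           call. = FALSE)
    knn <- list(idx = knn$idx[, seq_len(threshold), drop = FALSE],
                dist = knn$dist[, seq_len(threshold), drop = FALSE])
  }
  Matrix::sparseMatrix(
    i = rep(seq_len(n), each = threshold),
    j = as.integer(t(knn$idx)),
    x = as.numeric(t(knn$dist)),
    dims = c(n, n))
}

#' Build the sparse spatial smoothing operator
#'
#' Turns a sparse kNN distance matrix into the smoothing operator used on the
#' principal components: the diagonal is filled with a small distance
#' \eqn{\alpha} (so self-weights are defined), stored distances are converted
#' to weights — inverse distance \eqn{w = 1/d^\beta} by default, or a
#' gaussian / quadratic (Epanechnikov) kernel — and each column is divided by
#' its maximum stored value. Absent (thresholded) pairs stay exactly zero.
#'
#' \eqn{\beta = 0} gives a rectangular kernel (all retained weights equal);
#' larger \eqn{\beta} concentrates weight on the closest neighbours, e.g.
#' \eqn{\beta = 2} matches the dilution of a secreted molecule.
#'
#' @param D sparse distance matrix from [knn_sparse_distances()].
#' @param beta inverse-distance power (default 2, \code{>= 0}).
#' @param alpha_mode diagonal fill: \code{"row_min"} (minimum stored
#'   off-diagonal distance of the row, the default), \code{"column_min"}, or
#'   \code{"half_min"} (half the row minimum; suited to Visium arrays).
#' @param weighting \code{"inverse_distance"}, \code{"gaussian"} or
#'   \code{"quadratic"}.
#' @param bandwidth kernel bandwidth (kernel weightings only); default is the
#'   mean retained-neighbour distance.
#' @param normalize \code{"column"} (as specified for the method) or
#'   \code{"row"} (experimental variant).
#'
#' @return an n x n \code{dgCMatrix} of weights; every non-empty column has
#'   maximum 1 under column normalization.
#' @export
build_weights <- function(D, beta = 2,
                          alpha_mode = c("row_min", "column_min", "half_min"),
                          weighting = c("inverse_distance", "gaussian",
                                        "quadratic"),
                          bandwidth = NULL,
                          normalize = c("column", "row")) {
  alpha_mode <- match.arg(alpha_mode)
  weighting <- match.arg(weighting)
  normalize <- match.arg(normalize)
  if (beta < 0 || !is.finite(beta)) stop("beta must be finite and >= 0",
                                         call. = FALSE)
  T <- methods::as(D, "TsparseMatrix")
  i <- T@i + 1L; j <- T@j + 1L; d <- T@x
  off <- i != j
  i <- i[off]; j <- j[off]; d <- d[off]
  n <- nrow(D)
  if (any(d == 0) && weighting == "inverse_distance" && beta > 0)
    stop("zero distances found: duplicate coordinates; jitter or deduplicate ",
         "locations before building inverse-distance weights", call. = FALSE)

  row_min <- rep(Inf, n); col_min <- rep(Inf, n)
  for (kk in seq_along(d)) {
    if (d[kk] < row_min[i[kk]]) row_min[i[kk]] <- d[kk]
    if (d[kk] < col_min[j[kk]]) col_min[j[kk]] <- d[kk]
  }
  alpha <- switch(alpha_mode,
                  row_min = row_min,
                  column_min = col_min,
                  half_min = row_min / 2)
  alpha[!is.finite(alpha)] <- 0

  ii <- c(i, seq_len(n)); jj <- c(j, seq_len(n)); dd <- c(d, alpha)
  if (is.null(bandwidth)) bandwidth <- mean(d)
  if (weighting != "inverse_distance" && (!is.finite(bandwidth) ||
                                          bandwidth <= 0))
    stop("bandwidth must be positive for kernel weightings", call. = FALSE)

  w <- switch(weighting,
    inverse_distance = if (beta == 0) rep(1, length(dd)) else 1 / dd^beta,
    gaussian = exp(-dd^2 / (2 * bandwidth^2)),
    quadratic = pmax(0, 1 - (dd / bandwidth)^2))

  keep <- w > 0
  W <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = w[keep],
                            dims = c(n, n))
  if (normalize == "column") {
    mx <- apply_margin_max(W, 2L)
    empty <- mx == 0
    if (any(empty))
      warning(sum(empty), " column(s) empty after kernel truncation; ",
              "left all-zero")
    mx[empty] <- 1
    W <- W %*% Matrix::Diagonal(x = 1 / mx)
  } else {
    mx <- apply_margin_max(W, 1L)
    mx[mx == 0] <- 1
    W <- Matrix::Diagonal(x = 1 / mx) %*% W
  }
  methods::as(W, "CsparseMatrix")
}

# max of stored entries per column (margin=2) or row (margin=1)
apply_margin_max <- function(W, margin) {
  T <- methods::as(W, "TsparseMatrix")
  n <- if (margin == 2L) ncol(W) else nrow(W)
  key <- if (margin == 2L) T@j + 1L else T@i + 1L
  out <- rep(0, n)
  if (length(T@x)) {
    agg <- tapply(T@x, key, max)
    out[as.integer(names(agg))] <- agg
  }
  out
}

#' Spatial smoothing operator from coordinates
#'
#' Convenience wrapper: [knn_sparse_distances()] followed by
#' [build_weights()].
#'
#' @inheritParams knn_sparse_distances
#' @inheritParams build_weights
#' @return an n x n sparse weight matrix.
#' @export
spatial_weights <- function(coords, threshold, beta = 2,
                            metric = c("euclidean", "manhattan"),
                            alpha_mode = c("row_min", "column_min",
                                           "half_min"),
                            weighting = c("inverse_distance", "gaussian",
                                          "quadratic"),
                            bandwidth = NULL,
                            normalize = c("column", "row"),
                            knn = NULL) {
  D <- knn_sparse_distances(coords, threshold, match.arg(metric), knn = knn)
  build_weights(D, beta = beta, alpha_mode = match.arg(alpha_mode),
                weighting = match.arg(weighting), bandwidth = bandwidth,
                normalize = match.arg(normalize))
}

#' Apply the smoothing operator to a matrix
#'
#' Computes the sparse product \code{DI \%*\% M}: each output row is the
#' weighted sum of the rows of \code{M} over the location's retained
#' neighbourhood. No implicit row normalization is applied.
#'
#' @param DI n x n sparse weight matrix.
#' @param M n x p numeric matrix (e.g. PC scores or covariates).
#' @return n x p dense matrix.
#' @export
smooth_matrix <- function(DI, M) {
  M <- as.matrix(M)
  if (nrow(DI) != nrow(M))
    stop("DI and M must have the same number of rows", call. = FALSE)
  as.matrix(DI %*% M)
}
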