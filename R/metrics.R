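#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions via the standard
#' contingency-table formula; 1 for identical partitions (up to relabelling),
#' about 0 for independent ones, and possibly negative for partitions that
#' agree less than chance.
#'
#' @param a,b equal-length label vectors (any atomic type).
#' @return a number in \code{[-1, 1]}.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors must have equal length", call. = FALSE)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_ij <- sum_a * sum_b / choose(n, 2)
  max_ij <- (sum_a + sum_b) / 2
  if (max_ij == exp_ij) return(1)          # both partitions trivial
  (sum_ij - exp_ij) / (max_ij - exp_ij)
}

#' Moran's I spatial autocorrelation
#'
#' Global Moran's I with row-standardized spatial weights, computed with
#' sparse operations: \eqn{I = (n / S_0) \, z^T W z / z^T z} with \code{z}
#' the centred values. Weights default to a binary kNN neighbourhood
#' (\code{spatial_neighbors} nearest locations), row-standardized; a custom
#' sparse weight matrix can be supplied instead. Under spatial randomness
#' the expectation is \code{-1/(n-1)}.
#'
#' For a label vector (factor or \code{is_labels = TRUE}), I is computed on
#' each cluster-indicator variable and averaged weighted by cluster size.
#'
#' @param values numeric n-vector, or cluster labels.
#' @param coords n x 2 coordinates (ignored when \code{W} is supplied).
#' @param spatial_neighbors k for the kNN weights (default 6).
#' @param W optional n x n sparse spatial weight matrix.
#' @param row_standardize divide each row of \code{W} by its sum
#'   (default \code{TRUE}).
#' @param is_labels treat \code{values} as cluster labels.
#' @return Moran's I (a single number).
#' @export
morans_i <- function(values, coords = NULL, spatial_neighbors = 6, W = NULL,
                     row_standardize = TRUE, is_labels = is.factor(values)) {
  if (is.null(W)) {
    if (is.null(coords)) stop("supply coords or W", call. = FALSE)
    nn <- knn_neighbors(coords, spatial_neighbors)
    n <- nrow(nn$idx)
    W <- Matrix::sparseMatrix(i = rep(seq_len(n), times = spatial_neighbors),
                              j = as.integer(nn$idx), x = 1,
                              dims = c(n, n))
  }
  n <- nrow(W)
  if (row_standardize) {
    rs <- Matrix::rowSums(W)
    rs[rs == 0] <- 1
    W <- Matrix::Diagonal(x = 1 / rs) %*% W
  }
  S0 <- sum(W)
  moran_one <- function(x) {
    z <- x - mean(x)
    denom <- sum(z^2)
    if (denom == 0)
      stop("Moran's I is undefined for constant values", call. = FALSE)
    (n / S0) * sum(z * as.numeric(W %*% z)) / denom
  }
  if (is_labels) {
    labs <- as.integer(factor(values))
    ks <- sort(unique(labs))
    if (length(ks) < 2)
      stop("Moran's I is undefined for a single cluster", call. = FALSE)
    sizes <- tabulate(labs)[ks]
    is_ <- vapply(ks, function(k) moran_one(as.numeric(labs == k)),
                  numeric(1))
    sum(is_ * sizes) / sum(sizes)
  } else {
    moran_one(as.numeric(values))
  }
}

#' CHAOS score of a spatial clustering
#'
#' Spatial continuity / compactness: coordinates are standardized to zero
#' mean and unit variance per axis, and for every location the distance to
#' its nearest neighbour *within the same cluster* is computed; CHAOS is the
#' sum of these distances divided by n. Lower values mean more contiguous,
#' compact clusters. Singleton clusters have no within-cluster neighbour and
#' are skipped with a warning.
#'
#' @param labels cluster labels (length n).
#' @param coords n x 2 coordinates.
#' @param standardize standardize coordinates first (default \code{TRUE};
#'   disabling it is useful for closed-form checks on unit grids).
#' @return non-negative number.
#' @export
chaos_score <- function(labels, coords, standardize = TRUE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(labels) != n)
    stop("labels and coords must align", call. = FALSE)
  if (standardize) {
    coords <- scale(coords)
    coords[, attr(coords, "scaled:scale") == 0] <- 0
  }
  total <- 0
  for (k in unique(labels)) {
    sel <- which(labels == k)
    if (length(sel) < 2L) {
      warning("cluster ", k, " is a singleton; skipped in CHAOS")
      next
    }
    nn <- knn_neighbors(coords[sel, , drop = FALSE], 1L)
    total <- total + sum(nn$dist)
  }
  total / n
}

#' One-parameter-at-a-time sweep over smoothing parameters
#'
#' Reruns smoothing and clustering over a grid of kNN thresholds and
#' inverse-distance powers, holding the first-stage PCA fixed (smoothing does
#' not require re-decomposition) and the neighbour search cached at the
#' largest threshold. Records cluster count, ARI against ground truth when
#' available, Moran's I of the labels and the CHAOS score for every
#' combination.
#'
#' @param X n x m normalized expression matrix or \code{spatial_expr}.
#' @param coords n x 2 coordinates.
#' @param knn_grid integer vector of smoothing thresholds.
#' @param beta_grid numeric vector of inverse-distance powers.
#' @param methods character vector of clustering methods
#'   (see [cluster_embedding()]).
#' @param truth optional ground-truth labels; also sets the default
#'   \code{target_k}.
#' @param p components for the shared first-stage PCA (default 20).
#' @param target_k desired cluster count (default: number of truth classes).
#' @param graph_neighbors embedding-graph neighbours (default 10).
#' @param morans_neighbors spatial neighbours for the Moran's I weights
#'   (default 6).
#' @param seed RNG seed shared by the solver and partitioners.
#'
#' @return long-format data.frame with columns \code{threshold}, \code{beta},
#'   \code{method}, \code{k}, \code{ari}, \code{morans_i}, \code{chaos}.
#' @export
parameter_sweep <- function(X, coords = NULL, knn_grid, beta_grid,
                            methods = "louvain", truth = NULL, p = 20,
                            target_k = NULL, graph_neighbors = 10,
                            morans_neighbors = 6, seed = 1) {
  if (inherits(X, "spatial_expr")) {
    coords <- X$coords
    X <- X$X
  }
  if (!length(knn_grid) || !length(beta_grid))
    stop("grids must be nonempty", call. = FALSE)
  if (!is.null(truth) && is.null(target_k))
    target_k <- length(unique(truth))
  s1 <- randomized_pca(X, p = min(p, ncol(X), nrow(X)), seed = seed)
  nn <- knn_neighbors(coords, max(knn_grid))
  rows <- list()
  for (thr in knn_grid) {
    D <- knn_sparse_distances(coords, thr, knn = nn)
    for (be in beta_grid) {
      DI <- build_weights(D, beta = be)
      Ps <- smooth_matrix(DI, s1$P)
      for (mth in methods) {
        labels <- cluster_embedding(Ps, method = mth,
                                    graph_neighbors = graph_neighbors,
                                    target_k = target_k, seed = seed)
        mi <- if (max(labels) > 1)
          morans_i(labels, coords, morans_neighbors, is_labels = TRUE)
        else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          threshold = thr, beta = be, method = mth, k = max(labels),
          ari = if (is.null(truth)) NA_real_
                else adjusted_rand_index(labels, truth),
          morans_i = mi,
          chaos = chaos_score(labels, coords),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
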