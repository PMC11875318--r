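#' Spatially smoothed randomized PCA
#'
#' The core two-stage procedure. Stage one performs randomized PCA on the
#' normalized expression matrix and smooths the scores with the sparse
#' kNN inverse-distance operator built from the tissue coordinates
#' (\code{Ps = DI \%*\% P}). When location-level covariates \code{Y} are
#' supplied, each covariate is standardized, optionally smoothed with the same
#' operator, appended to the smoothed scores, and a second randomized PCA of
#' \code{[Ps, Ys]} yields covariate-integrated components \code{Pc}. Keeping
#' the covariates out of the first PCA prevents their signal from being
#' diluted among thousands of genes and decouples their smoothing from that
#' of the expression data.
#'
#' @param X n x m normalized expression matrix (dense or sparse), or a
#'   \code{spatial_expr} object from [normalize_counts()] (in which case
#'   \code{coords} is taken from it).
#' @param coords n x 2 spatial coordinates (ignored when \code{X} is a
#'   \code{spatial_expr}).
#' @param Y optional n x b matrix/data.frame of location-level covariates
#'   (e.g. local cell density, library size, cell volume).
#' @param p number of smoothed components (default 20).
#' @param threshold number of spatial nearest neighbours retained in the
#'   smoothing operator (default 10).
#' @param beta inverse-distance power (default 2).
#' @param covariate_smooth logical, recycled across covariates: smooth this
#'   covariate with \code{DI} before the second stage? Use \code{FALSE} for
#'   covariates that already encode spatial structure (e.g. local density).
#' @param weights optional precomputed n x n smoothing operator; overrides
#'   \code{threshold}/\code{beta}/kernel arguments (useful for injecting an
#'   identity operator or an operator reused across a sweep).
#' @param seed integer seed for the randomized solver (default 1).
#' @inheritParams build_weights
#' @inheritParams randomized_pca
#' @param metric spatial distance metric.
#'
#' @return An object of class \code{spca_embedding}: list with \code{Ps}
#'   (n x p smoothed scores), \code{W} (m x p loadings), \code{P} (unsmoothed
#'   scores), \code{x_means} (gene means), \code{ps_means} (column means of
#'   \code{Ps}), and when covariates are given \code{Ys}, \code{Pc},
#'   \code{Wc}; plus \code{stage}, \code{p}, \code{b} and the smoothing
#'   configuration.
#' @seealso [reconstruct_expression()], [cluster_embedding()]
#' @export
smoothed_pca <- function(X, coords = NULL, Y = NULL, p = 20, threshold = 10,
                         beta = 2, metric = c("euclidean", "manhattan"),
                         alpha_mode = c("row_min", "column_min", "half_min"),
                         weighting = c("inverse_distance", "gaussian",
                                       "quadratic"),
                         bandwidth = NULL, normalize = c("column", "row"),
                         covariate_smooth = TRUE, center = TRUE,
                         scale = FALSE, oversample = 10, power_iter = 2,
                         seed = 1, weights = NULL) {
  if (inherits(X, "spatial_expr")) {
    coords <- X$coords
    X <- X$X
  }
  if (is.null(weights) && is.null(coords))
    stop("coords are required unless a precomputed weights matrix is given",
         call. = FALSE)
  n <- nrow(X)
  if (!is.null(coords) && nrow(coords) != n)
    stop("X and coords must be row-aligned", call. = FALSE)
  if (!is.null(Y)) {
    Y <- as.matrix(Y)
    if (nrow(Y) != n) stop("X and Y must be row-aligned", call. = FALSE)
  }

  s1 <- randomized_pca(X, p = p, center = center, scale = scale,
                       oversample = oversample, power_iter = power_iter,
                       seed = seed)
  DI <- if (is.null(weights)) {
    spatial_weights(coords, threshold = threshold, beta = beta,
                    metric = match.arg(metric),
                    alpha_mode = match.arg(alpha_mode),
                    weighting = match.arg(weighting), bandwidth = bandwidth,
                    normalize = match.arg(normalize))
  } else weights
  if (nrow(DI) != n) stop("weights matrix does not match X", call. = FALSE)
  Ps <- smooth_matrix(DI, s1$P)

  emb <- list(Ps = Ps, W = s1$W, P = s1$P, d = s1$d,
              x_means = s1$center, ps_means = colMeans(Ps),
              stage = "two_stage", p = p, b = 0L,
              threshold = if (is.null(weights)) threshold else NA,
              beta = if (is.null(weights)) beta else NA, seed = seed)
  class(emb) <- "spca_embedding"
  if (is.null(Y)) return(emb)

  b <- ncol(Y)
  Yz <- standardize_covariates(Y)
  sm <- rep_len(as.logical(covariate_smooth), b)
  Ys <- Yz
  if (any(sm)) Ys[, sm] <- smooth_matrix(DI, Yz[, sm, drop = FALSE])
  M2 <- cbind(Ps, Ys)
  p2 <- min(p, ncol(M2))
  s2 <- randomized_pca(M2, p = p2, center = TRUE, scale = FALSE,
                       oversample = oversample, power_iter = power_iter,
                       seed = seed)
  r <- sum(s2$d > max(s2$d) * 1e-10)
  if (r < p2) {
    warning("requested ", p2, " second-stage components but [Ps, Ys] has ",
            "numerical rank ", r, "; truncating")
    s2$W <- s2$W[, seq_len(r), drop = FALSE]
    s2$P <- s2$P[, seq_len(r), drop = FALSE]
    s2$d <- s2$d[seq_len(r)]
  }
  emb$Ys <- Ys
  emb$Wc <- s2$W
  emb$Pc <- s2$P
  emb$stage2_means <- s2$center
  emb$b <- b
  emb
}

#' Single-stage PCA on expression merged with covariates
#'
#' The comparison configuration to the two-stage scheme of [smoothed_pca()]:
#' covariates are standardized and column-appended to the expression matrix,
#' a single randomized PCA is run on the merge, and the scores are then
#' spatially smoothed. With b covariates among m genes the covariate signal
#' competes with the full transcriptome for variance, which is exactly the
#' dilution the two-stage design avoids.
#'
#' @inheritParams smoothed_pca
#' @return an \code{spca_embedding} with \code{stage = "single_stage"}; its
#'   \code{W} has m + b rows (genes then covariates).
#' @export
single_stage_pca <- function(X, coords = NULL, Y, p = 20, threshold = 10,
                             beta = 2, metric = c("euclidean", "manhattan"),
                             alpha_mode = c("row_min", "column_min",
                                            "half_min"),
                             weighting = c("inverse_distance", "gaussian",
                                           "quadratic"),
                             bandwidth = NULL,
                             normalize = c("column", "row"),
                             center = TRUE, scale = FALSE, oversample = 10,
                             power_iter = 2, seed = 1, weights = NULL) {
  if (inherits(X, "spatial_expr")) {
    coords <- X$coords
    X <- X$X
  }
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) stop("X and Y must be row-aligned", call. = FALSE)
  Yz <- standardize_covariates(Y)
  M <- if (inherits(X, "sparseMatrix"))
    methods::as(cbind(X, Matrix::Matrix(Yz, sparse = TRUE)), "CsparseMatrix")
  else cbind(as.matrix(X), Yz)
  emb <- smoothed_pca(M, coords = coords, Y = NULL, p = p,
                      threshold = threshold, beta = beta,
                      metric = match.arg(metric),
                      alpha_mode = match.arg(alpha_mode),
                      weighting = match.arg(weighting), bandwidth = bandwidth,
                      normalize = match.arg(normalize), center = center,
                      scale = scale, oversample = oversample,
                      power_iter = power_iter, seed = seed, weights = weights)
  emb$stage <- "single_stage"
  emb$b <- ncol(Y)
  emb
}

# center and scale each covariate to unit variance; constant columns -> 0
standardize_covariates <- function(Y) {
  Y <- as.matrix(Y)
  mu <- colMeans(Y)
  sdv <- apply(Y, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- Inf   # constant covariate vanishes
  sweep(sweep(Y, 2L, mu, "-"), 2L, sdv, "/")
}

#' @export
print.spca_embedding <- function(x, ...) {
  cat("spca_embedding (", x$stage, "): ", nrow(x$Ps), " locations, ",
      ncol(x$Ps), " smoothed components", sep = "")
  if (x$b > 0) cat(", ", x$b, " covariates", sep = "")
  cat("\n  smoothing: threshold = ", x$threshold, ", beta = ", x$beta,
      "\n", sep = "")
  invisible(x)
}
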