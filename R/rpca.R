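#' Randomized PCA of a (sparse) expression matrix
#'
#' Top-p principal components via a randomized range finder (Gaussian sketch,
#' QR re-orthonormalized power iterations, small exact SVD of the projected
#' matrix). Centering (and optional gene scaling) is performed implicitly
#' through rank-one corrections, so a sparse input is never densified.
#'
#' With \code{oversample} large enough that the sketch spans the full column
#' space (\code{p + oversample >= min(n, m)}) the result equals the exact PCA
#' up to floating point error; otherwise the power iterations drive the
#' principal-subspace error down geometrically in the spectral gap.
#'
#' A deterministic sign convention is applied: the largest-magnitude loading
#' of each component is positive, so loadings are comparable across runs and
#' implementations.
#'
#' @param X n x m numeric matrix, dense or \code{dgCMatrix}.
#' @param p number of components (\code{1 <= p <= min(n, m)}).
#' @param center subtract column means (default \code{TRUE}).
#' @param scale divide columns by their standard deviation (default
#'   \code{FALSE}).
#' @param oversample extra sketch columns beyond \code{p} (default 10).
#' @param power_iter number of power iterations (default 2).
#' @param seed integer seed for the Gaussian sketch; \code{NULL} leaves the
#'   RNG state alone.
#'
#' @return list with \code{W} (m x p loadings, orthonormal columns), \code{P}
#'   (n x p scores of the centered/scaled matrix), \code{d} (singular values),
#'   \code{center} (column means used), \code{scale} (column scales used),
#'   \code{var_explained} (per-component variance \code{d^2/(n-1)}).
#' @export
randomized_pca <- function(X, p, center = TRUE, scale = FALSE,
                           oversample = 10, power_iter = 2, seed = NULL) {
  n <- nrow(X); m <- ncol(X)
  p <- as.integer(p)
  if (p < 1L || p > min(n, m))
    stop("p must satisfy 1 <= p <= min(n, m)", call. = FALSE)
  if (oversample < 0) stop("oversample must be >= 0", call. = FALSE)
  vals <- if (inherits(X, "sparseMatrix")) X@x else X
  if (length(vals) && !all(is.finite(vals)))
    stop("X must be finite", call. = FALSE)

  mu <- if (center) as.numeric(Matrix::colMeans(X)) else numeric(m)
  if (scale) {
    ex2 <- as.numeric(Matrix::colMeans(X^2))
    sdv <- sqrt(pmax(ex2 - (as.numeric(Matrix::colMeans(X)))^2, 0) *
                  n / (n - 1))
    sdv[sdv == 0] <- 1
  } else {
    sdv <- rep(1, m)
  }
  mus <- mu / sdv

  # Xc %*% V  and  t(Xc) %*% U  with Xc = (X - 1 mu') diag(1/sdv), implicit
  amult <- function(V) {
    cv <- drop(crossprod(mus, V))
    as.matrix(X %*% (V / sdv)) - matrix(cv, n, ncol(V), byrow = TRUE)
  }
  atmult <- function(U) {
    as.matrix(Matrix::crossprod(X, U)) / sdv - outer(mus, colSums(U))
  }

  l <- min(p + as.integer(oversample), n, m)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
    set.seed(as.integer(seed))
  }
  Omega <- matrix(stats::rnorm(m * l), m, l)
  Q <- qr.Q(qr(amult(Omega)))
  for (it in seq_len(power_iter)) {
    Q <- qr.Q(qr(atmult(Q)))
    Q <- qr.Q(qr(amult(Q)))
  }
  B <- t(atmult(Q))                       # l x m projected matrix
  sv <- svd(B, nu = 0, nv = p)
  W <- sv$v[, seq_len(p), drop = FALSE]
  # deterministic signs: largest-magnitude loading positive
  for (jc in seq_len(p)) {
    piv <- which.max(abs(W[, jc]))
    if (W[piv, jc] < 0) W[, jc] <- -W[, jc]
  }
  P <- amult(W)
  rownames(W) <- colnames(X)
  list(W = W, P = P, d = sv$d[seq_len(p)], center = mu, scale = sdv,
       var_explained = sv$d[seq_len(p)]^2 / (n - 1))
}
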