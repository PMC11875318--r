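# Independent dense, loop-based oracles used to pin down the sparse /
# randomized implementations. These deliberately avoid the package's own
# code paths: exact svd(), dense distance matrices, explicit per-entry loops.

# exact PCA of the column-centered matrix, same sign convention
dense_pca <- function(X, p) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  sv <- svd(Xc)
  W <- sv$v[, seq_len(p), drop = FALSE]
  for (j in seq_len(p)) {
    piv <- which.max(abs(W[, j]))
    if (W[piv, j] < 0) W[, j] <- -W[, j]
  }
  list(W = W, P = Xc %*% W, d = sv$d[seq_len(p)], center = mu)
}

# dense transcription of the smoothing operator: kNN threshold, diagonal
# alpha = row minimum, inverse-distance weights, column-max standardization
dense_weights <- function(coords, threshold, beta) {
  n <- nrow(coords)
  Dfull <- as.matrix(stats::dist(coords))
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nb <- others[order(Dfull[i, others])[seq_len(threshold)]]
    D[i, nb] <- Dfull[i, nb]
  }
  for (i in seq_len(n)) D[i, i] <- min(D[i, D[i, ] > 0])
  DI <- matrix(0, n, n)
  if (beta == 0) DI[D > 0] <- 1 else DI[D > 0] <- 1 / D[D > 0]^beta
  for (j in seq_len(n)) DI[, j] <- DI[, j] / max(DI[, j])
  DI
}

# full dense two-stage pipeline (optional covariates), explicit steps
dense_smoothed_pca <- function(X, coords, p, threshold, beta, Y = NULL,
                               smooth_cov = TRUE) {
  s1 <- dense_pca(X, p)
  DI <- dense_weights(coords, threshold, beta)
  Ps <- DI %*% s1$P
  out <- list(Ps = Ps, W = s1$W, P = s1$P, x_means = s1$center,
              ps_means = colMeans(Ps), DI = DI)
  if (!is.null(Y)) {
    Y <- as.matrix(Y)
    Yz <- sweep(Y, 2L, colMeans(Y), "-")
    Yz <- sweep(Yz, 2L, apply(Y, 2L, stats::sd), "/")
    Ys <- if (smooth_cov) DI %*% Yz else Yz
    s2 <- dense_pca(cbind(Ps, Ys), p)
    out$Ys <- Ys
    out$Wc <- s2$W
    out$Pc <- s2$P
  }
  out
}

# literal per-entry transcription of the reduced-rank reconstruction with
# quantile thresholding and optional variance rescaling
dense_reconstruct <- function(X, den, q, scale) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X); p <- ncol(den$Ps)
  if (!is.null(den$Pc)) {
    R <- den$Pc %*% t(den$Wc)
    Ps_r <- R[, seq_len(p), drop = FALSE]
    for (j in seq_len(p)) Ps_r[, j] <- Ps_r[, j] + den$ps_means[j]
  } else {
    Ps_r <- den$Ps
  }
  Xr <- Ps_r %*% t(den$W)
  for (i in seq_len(m)) Xr[, i] <- Xr[, i] + den$x_means[i]
  for (i in seq_len(m)) {
    xq <- stats::quantile(Xr[, i], q, names = FALSE)
    col <- numeric(n)
    for (j in seq_len(n)) {
      col[j] <- if (abs(Xr[j, i]) >= abs(xq)) Xr[j, i]
                else if (X[j, i] > 0) X[j, i] else 0
    }
    if (scale) {
      so <- stats::sd(X[X[, i] > 0, i])
      sr <- stats::sd(col[col > 0])
      if (sum(X[, i] > 0) >= 2 && sum(col > 0) >= 2)
        col <- col * (so / max(sr, 1e-10))
    }
    Xr[, i] <- col
  }
  Xr
}

# sine of the largest principal angle between column spaces
subspace_angle <- function(A, B) {
  qa <- qr.Q(qr(as.matrix(A)))
  qb <- qr.Q(qr(as.matrix(B)))
  sv <- svd(crossprod(qa, qb))$d
  sqrt(max(0, 1 - min(sv)^2))
}

# small count fixture with spatial structure, non-negative
toy_counts <- function(n = 20, m = 10, seed = 7) {
  set.seed(seed)
  X <- matrix(stats::rpois(n * m, 3) + 0, n, m)
  coords <- matrix(stats::runif(2 * n), n, 2)
  list(X = X, coords = coords)
}

# map retained location ids of a filtered object back to simulation truth
sim_truth <- function(sim, filtered) {
  sim$domain_labels[match(filtered$location_ids, rownames(sim$counts))]
}
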