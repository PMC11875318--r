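#' Reduced-rank reconstruction of gene expression
#'
#' Projects the expression matrix onto the spatially smoothed components and
#' back (\code{Xr = Ps \%*\% t(W) + gene means}), borrowing signal across
#' correlated genes and neighbouring locations to de-noise sparse
#' measurements. When the embedding carries covariate-integrated components,
#' the smoothed PCs are first themselves reconstructed from \code{Pc} and
#' \code{Wc} (the covariate block is discarded and the \code{Ps} column means
#' are added back) so the covariates inform the reconstruction.
#'
#' Each gene is then passed through [threshold_scale_gene()]: reconstructed
#' values below the gene's magnitude cutoff revert to the observed value where
#' that was positive and to exactly zero where it was zero, and the nonzero
#' values are optionally rescaled to match the observed expression variance.
#'
#' @param X the n x m normalized matrix the embedding was fitted on (or the
#'   \code{spatial_expr} holding it).
#' @param emb an \code{spca_embedding} from [smoothed_pca()].
#' @param q quantile probability in \code{[0, 1]} for the per-gene magnitude
#'   cutoff (default 0.3); \code{q = 0} retains every reconstructed value.
#' @param scale rescale each gene so the standard deviation of its nonzero
#'   reconstructed values matches that of its nonzero observed values
#'   (default \code{TRUE}).
#' @param sigma_floor denominator guard for the scaling factor
#'   (default \code{1e-10}).
#' @param clamp_nonneg set surviving negative reconstructed values to zero
#'   (off by default; the plain method keeps them).
#'
#' @return An object of class \code{spca_reconstruction}: list with \code{Xr}
#'   (n x m dense matrix) and \code{audit}, a data.frame with one row per
#'   gene (quantile cutoff, counts of entries kept / replaced by the observed
#'   value / zeroed, scaling factor, and whether scaling was skipped).
#' @export
reconstruct_expression <- function(X, emb, q = 0.3, scale = TRUE,
                                   sigma_floor = 1e-10,
                                   clamp_nonneg = FALSE) {
  if (inherits(X, "spatial_expr")) X <- X$X
  stopifnot(inherits(emb, "spca_embedding"))
  if (identical(emb$stage, "single_stage"))
    stop("reconstruction requires a covariate-free or two-stage embedding ",
         "(single-stage loadings mix genes and covariates)", call. = FALSE)
  if (q < 0 || q > 1) stop("q must be in [0, 1]", call. = FALSE)
  if (is.null(emb$x_means) || is.null(emb$ps_means))
    stop("embedding is missing stored column means", call. = FALSE)
  n <- nrow(X); m <- ncol(X)
  p <- ncol(emb$Ps)
  if (nrow(emb$Ps) != n || nrow(emb$W) != m)
    stop("embedding dimensions do not match X", call. = FALSE)

  if (!is.null(emb$Pc)) {
    R <- emb$Pc %*% t(emb$Wc)                  # reconstruct [Ps, Ys]
    Ps_r <- R[, seq_len(p), drop = FALSE]      # drop covariate block
    Ps_r <- sweep(Ps_r, 2L, emb$ps_means, "+") # add back Ps column means
  } else {
    Ps_r <- emb$Ps
  }
  Xr <- Ps_r %*% t(emb$W)
  Xr <- sweep(Xr, 2L, emb$x_means, "+")

  Xd <- as.matrix(X)
  audit <- data.frame(gene = colnames(Xd) %||% paste0("gene", seq_len(m)),
                      cutoff = NA_real_, kept = NA_integer_,
                      replaced = NA_integer_, zeroed = NA_integer_,
                      s = NA_real_, scale_skipped = FALSE,
                      stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    res <- threshold_gene_impl(Xd[, i], Xr[, i], q = q, scale = scale,
                               sigma_floor = sigma_floor,
                               clamp_nonneg = clamp_nonneg)
    Xr[, i] <- res$values
    audit$cutoff[i] <- res$cutoff
    audit$kept[i] <- res$kept
    audit$replaced[i] <- res$replaced
    audit$zeroed[i] <- res$zeroed
    audit$s[i] <- res$s
    audit$scale_skipped[i] <- res$scale_skipped
  }
  dimnames(Xr) <- dimnames(Xd)
  structure(list(Xr = Xr, audit = audit, q = q, scale = scale),
            class = "spca_reconstruction")
}

#' Threshold and rescale one reconstructed gene
#'
#' The per-gene adaptive rule: compute the q-th quantile \code{xq} of the
#' reconstructed values (linear-interpolation quantile, \code{type = 7});
#' keep reconstructed entries whose magnitude is at least \code{|xq|};
#' elsewhere fall back to the observed value when it was positive, and to
#' exactly zero when the observed value was zero. If \code{scale} is on, the
#' gene is multiplied by \code{s = sd(observed nonzero) / max(sd(result
#' nonzero), sigma_floor)}, computed on the post-threshold values; scaling is
#' skipped (and flagged) when either nonzero population has fewer than two
#' entries, where a standard deviation is undefined.
#'
#' @param x observed n-vector (non-negative normalized expression).
#' @param xr reconstructed n-vector.
#' @inheritParams reconstruct_expression
#' @return the thresholded (and possibly rescaled) n-vector, with attributes
#'   \code{cutoff} and \code{s}.
#' @export
threshold_scale_gene <- function(x, xr, q, scale = FALSE,
                                 sigma_floor = 1e-10, clamp_nonneg = FALSE) {
  res <- threshold_gene_impl(x, xr, q, scale, sigma_floor, clamp_nonneg)
  structure(res$values, cutoff = res$cutoff, s = res$s)
}

threshold_gene_impl <- function(x, xr, q, scale, sigma_floor, clamp_nonneg) {
  if (length(x) != length(xr))
    stop("x and xr must have the same length", call. = FALSE)
  xq <- stats::quantile(xr, probs = q, names = FALSE, type = 7)
  keep <- abs(xr) >= abs(xq)
  out <- ifelse(keep, xr, ifelse(x > 0, x, 0))
  kept <- sum(keep)
  replaced <- sum(!keep & x > 0)
  zeroed <- sum(!keep & x == 0)
  s <- NA_real_
  skipped <- FALSE
  if (scale) {
    xs <- x[x > 0]
    os <- out[out > 0]
    if (length(xs) >= 2L && length(os) >= 2L) {
      s <- stats::sd(xs) / max(stats::sd(os), sigma_floor)
      out <- s * out
    } else {
      skipped <- TRUE
    }
  }
  if (clamp_nonneg) out[out < 0] <- 0
  list(values = out, cutoff = xq, kept = kept, replaced = replaced,
       zeroed = zeroed, s = s, scale_skipped = skipped)
}

#' @export
print.spca_reconstruction <- function(x, ...) {
  cat("spca_reconstruction: ", nrow(x$Xr), " x ", ncol(x$Xr),
      " (q = ", x$q, ", scale = ", x$scale, ")\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
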