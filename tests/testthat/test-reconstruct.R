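test_that("per-gene thresholding follows the quantile rule", {
  v <- threshold_scale_gene(c(0, 3, 0), c(0.05, 2.9, -0.2), q = 0.9)
  expect_equal(attr(v, "cutoff"), 2.33, tolerance = 1e-12)
  expect_equal(as.numeric(v), c(0, 2.9, 0))

  v2 <- threshold_scale_gene(c(1, 2, 3), c(1, 2, 3), q = 0, scale = TRUE)
  expect_equal(as.numeric(v2), c(1, 2, 3))
  expect_equal(attr(v2, "s"), 1)

  # a single nonzero observed value: sd undefined, scaling skipped
  v3 <- threshold_scale_gene(c(0, 5, 0), c(0.1, 4, 0.2), q = 0.9,
                             scale = TRUE)
  expect_true(is.na(attr(v3, "s")))
})

test_that("identity smoothing + full rank + q = 0 is lossless", {
  tc <- toy_counts(20, 10, seed = 2)
  emb <- smoothed_pca(tc$X, tc$coords, p = 10,
                      weights = Matrix::Diagonal(20), seed = 3)
  rec <- reconstruct_expression(tc$X, emb, q = 0, scale = FALSE)
  expect_equal(rec$Xr, tc$X, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("reconstruction matches the literal transcription oracle", {
  tc <- toy_counts(20, 10, seed = 5)
  set.seed(6)
  Y <- cbind(rnorm(20), runif(20))
  emb <- smoothed_pca(tc$X, tc$coords, Y = Y, p = 4, threshold = 3,
                      beta = 2, seed = 7)
  den <- dense_smoothed_pca(tc$X, tc$coords, p = 4, threshold = 3, beta = 2,
                            Y = Y)
  for (q in c(0, 0.3, 0.9)) {
    rec <- reconstruct_expression(tc$X, emb, q = q, scale = TRUE)
    expect_equal(rec$Xr, dense_reconstruct(tc$X, den, q, TRUE),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # covariate-free route against the same oracle
  emb0 <- smoothed_pca(tc$X, tc$coords, p = 4, threshold = 3, beta = 2,
                       seed = 7)
  den0 <- dense_smoothed_pca(tc$X, tc$coords, p = 4, threshold = 3, beta = 2)
  rec0 <- reconstruct_expression(tc$X, emb0, q = 0.3, scale = TRUE)
  expect_equal(rec0$Xr, dense_reconstruct(tc$X, den0, 0.3, TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero pattern, q-monotonicity and the scaling contract hold", {
  tc <- toy_counts(40, 12, seed = 9)
  emb <- smoothed_pca(tc$X, tc$coords, p = 5, threshold = 4, beta = 1,
                      seed = 10)
  for (q in c(0, 0.2, 0.5, 0.8, 1)) {
    rec <- reconstruct_expression(tc$X, emb, q = q, scale = FALSE)
    # zeros with sub-cutoff reconstruction are exactly zero
    raw <- emb$Ps %*% t(emb$W) +
      matrix(emb$x_means, 40, 12, byrow = TRUE)
    for (i in seq_len(12)) {
      cut <- abs(quantile(raw[, i], q, names = FALSE))
      sub <- tc$X[, i] == 0 & abs(raw[, i]) < cut
      expect_true(all(rec$Xr[sub, i] == 0))
    }
  }
  # retained set shrinks with q on a non-negative reconstruction (the
  # magnitude cutoff is monotone only when the quantile itself is)
  set.seed(77)
  xr <- abs(rnorm(60, 1))
  x <- rpois(60, 2) + 0
  prev <- NULL
  for (q in c(0, 0.25, 0.5, 0.75, 1)) {
    v <- threshold_scale_gene(x, xr, q = q)
    kept_idx <- which(as.numeric(v) == xr)
    if (!is.null(prev)) expect_true(all(kept_idx %in% prev))
    prev <- kept_idx
  }
  recs <- reconstruct_expression(tc$X, emb, q = 0.3, scale = TRUE)
  for (i in seq_len(12)) {
    xr <- recs$Xr[, i]
    x <- tc$X[, i]
    if (!recs$audit$scale_skipped[i] && sum(xr > 0) >= 2 && sum(x > 0) >= 2)
      expect_equal(sd(xr[xr > 0]), sd(x[x > 0]), tolerance = 1e-8)
  }
  expect_equal(recs$audit$kept + recs$audit$replaced + recs$audit$zeroed,
               rep(40L, 12))
})

test_that("q = 0 with scaling off is the exact low-rank round trip", {
  # on a non-negative reconstruction the q = 0 cutoff is the minimum value
  # and every entry is retained, so Xr is exactly Ps W' + means
  tc <- toy_counts(25, 8, seed = 13)
  emb <- smoothed_pca(tc$X, tc$coords, p = 4, threshold = 3, seed = 14)
  direct <- emb$Ps %*% t(emb$W) + matrix(emb$x_means, 25, 8, byrow = TRUE)
  shift <- max(0, -min(direct)) + 1      # make the low-rank surface positive
  rec <- reconstruct_expression(tc$X + shift,
                                local({
                                  e <- emb
                                  e$x_means <- e$x_means + shift
                                  e
                                }),
                                q = 0, scale = FALSE)
  expect_equal(rec$Xr, direct + shift, ignore_attr = TRUE)
  # entry-level identity: q = 0 keeps a non-negative reconstruction intact
  v <- threshold_scale_gene(c(1, 0, 2), c(0.5, 0.1, 2.2), q = 0)
  expect_equal(as.numeric(v), c(0.5, 0.1, 2.2))
})

test_that("invalid inputs are rejected", {
  tc <- toy_counts(15, 6, seed = 15)
  emb <- smoothed_pca(tc$X, tc$coords, p = 3, threshold = 2, seed = 16)
  expect_error(reconstruct_expression(tc$X, emb, q = 2), "in \\[0, 1\\]")
  expect_error(reconstruct_expression(tc$X[1:10, ], emb), "do not match")
  one <- single_stage_pca(tc$X, tc$coords, Y = cbind(rnorm(15)), p = 3,
                          threshold = 2, seed = 16)
  expect_error(reconstruct_expression(tc$X, one), "single-stage")
})
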