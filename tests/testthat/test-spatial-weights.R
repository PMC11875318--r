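test_that("kNN sparse distances match inspection on collinear points", {
  co <- cbind(c(0, 1, 3), c(0, 0, 0))
  D <- knn_sparse_distances(co, 1)
  expect_equal(D[1, 2], 1)
  expect_equal(D[2, 1], 1)
  expect_equal(D[3, 2], 2)
  expect_equal(Matrix::nnzero(D), 3L)
})

test_that("threshold n-1 reproduces the full off-diagonal distance matrix", {
  set.seed(5)
  co <- matrix(runif(24), 12, 2)
  D <- as.matrix(knn_sparse_distances(co, 11))
  full <- as.matrix(dist(co))
  expect_equal(D, full, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("kNN search matches a brute-force all-pairs sort", {
  set.seed(9)
  co <- matrix(runif(200), 100, 2)
  nn <- knn_neighbors(co, 5)
  full <- as.matrix(dist(co))
  for (i in c(1, 17, 50, 100)) {
    o <- order(full[i, -i])[1:5]
    expect_equal(nn$idx[i, ], (seq_len(100)[-i])[o])
    expect_equal(nn$dist[i, ], full[i, (seq_len(100)[-i])[o]],
                 ignore_attr = TRUE)
  }
  # manhattan metric against a hand-rolled oracle
  nn_m <- knn_neighbors(co, 3, metric = "manhattan")
  manh <- as.matrix(dist(co, method = "manhattan"))
  for (i in c(2, 60)) {
    o <- order(manh[i, -i])[1:3]
    expect_equal(nn_m$dist[i, ], manh[i, (seq_len(100)[-i])[o]],
                 ignore_attr = TRUE)
  }
})

test_that("two points at distance 2 give an all-ones operator", {
  co <- cbind(c(0, 2), c(0, 0))
  DI <- build_weights(knn_sparse_distances(co, 1), beta = 2)
  # pre-normalization every entry is 1/2^2; column max standardization -> 1
  expect_equal(unname(as.matrix(DI)), matrix(1, 2, 2))
})

test_that("beta = 0 yields the rectangular kernel", {
  set.seed(13)
  co <- matrix(runif(60), 30, 2)
  DI <- spatial_weights(co, threshold = 4, beta = 0)
  vals <- DI@x
  expect_true(all(vals == 1))
  expect_lte(Matrix::nnzero(DI), 30 * 5)
})

test_that("weights match the dense transcription of the algorithm", {
  set.seed(23)
  co <- matrix(runif(50), 25, 2)
  for (beta in c(0.5, 1, 2)) {
    DI <- spatial_weights(co, threshold = 3, beta = beta)
    expect_equal(as.matrix(DI), dense_weights(co, 3, beta),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("column standardization and sparsity invariants hold", {
  set.seed(31)
  co <- matrix(runif(160), 80, 2)
  DI <- spatial_weights(co, threshold = 6, beta = 2)
  cmax <- apply(as.matrix(DI), 2, max)
  expect_equal(unname(cmax), rep(1, 80))
  expect_lte(Matrix::nnzero(DI), 80 * 7)
  expect_true(all(DI@x > 0))
})

test_that("larger beta concentrates weight on near neighbours", {
  set.seed(37)
  co <- matrix(runif(40), 20, 2)
  ratio <- function(beta) {
    D <- knn_sparse_distances(co, 4)
    DI <- build_weights(D, beta = beta)
    d1 <- as.matrix(D)[1, ]
    w1 <- as.matrix(DI)[1, ]
    nb <- which(d1 > 0)
    w1[nb[which.max(d1[nb])]] / w1[nb[which.min(d1[nb])]]
  }
  r <- vapply(c(0, 0.5, 1, 2), ratio, numeric(1))
  expect_true(all(diff(r) < 0))
  expect_equal(r[1], 1)
})

test_that("kernel weightings behave and duplicates raise", {
  set.seed(41)
  co <- matrix(runif(40), 20, 2)
  DIg <- spatial_weights(co, threshold = 3, weighting = "gaussian")
  expect_true(all(DIg@x > 0 & DIg@x <= 1 + 1e-12))
  DIq <- spatial_weights(co, threshold = 3, weighting = "quadratic",
                         bandwidth = 1)
  expect_true(all(DIq@x > 0 & DIq@x <= 1 + 1e-12))
  # a too-narrow quadratic kernel truncates whole columns, with a warning
  expect_warning(spatial_weights(co, threshold = 3, weighting = "quadratic",
                                 bandwidth = 1e-4), "truncation")
  dup <- rbind(co, co[1, , drop = FALSE])
  expect_error(spatial_weights(dup, threshold = 2, beta = 2),
               "duplicate coordinates")
  # beta = 0 tolerates duplicates (rectangular kernel never divides)
  DI0 <- spatial_weights(dup, threshold = 2, beta = 0)
  expect_true(all(DI0@x == 1))
})

test_that("smoothing is the plain sparse product", {
  set.seed(43)
  co <- matrix(runif(100), 50, 2)
  M <- matrix(rnorm(250), 50, 5)
  expect_equal(smooth_matrix(Matrix::Diagonal(50), M), M,
               ignore_attr = TRUE)
  DI <- spatial_weights(co, threshold = 5, beta = 1)
  expect_equal(smooth_matrix(DI, M), as.matrix(DI) %*% M,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(smooth_matrix(DI, M[1:10, ]), "same number of rows")
})

test_that("row-normalized variant and error paths work", {
  set.seed(47)
  co <- matrix(runif(40), 20, 2)
  DIr <- spatial_weights(co, threshold = 3, beta = 2, normalize = "row")
  expect_equal(unname(apply(as.matrix(DIr), 1, max)), rep(1, 20))
  expect_error(knn_sparse_distances(co, 20), "smaller than")
  expect_error(knn_neighbors(cbind(c(0, NA), c(0, 1)), 1), "finite")
})
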