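test_that("adjusted Rand index reproduces worked values and invariances", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(3, 3, 1, 1, 2, 2)), 1)
  set.seed(1)
  b <- sample(1:3, 6, replace = TRUE)
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  expect_error(adjusted_rand_index(a, b[1:3]), "equal length")
  # cross-check against the independent implementation on random partitions
  for (i in 1:5) {
    x <- sample(1:4, 60, replace = TRUE)
    y <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), mclust::adjustedRandIndex(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Moran's I matches closed forms and the dense oracle", {
  # alternating chain with adjacency weights: I = -1 exactly
  n <- 12
  x <- rep(c(0, 1), n / 2)
  W <- Matrix::sparseMatrix(i = c(1:(n - 1), 2:n), j = c(2:n, 1:(n - 1)),
                            x = 1, dims = c(n, n))
  expect_equal(morans_i(x, W = W), -1)

  # two half-planes on a grid: strong positive autocorrelation
  g <- as.matrix(expand.grid(x = 1:20, y = 1:20))
  lab <- as.numeric(g[, 1] > 10)
  i_hp <- morans_i(lab, g, spatial_neighbors = 4)
  expect_gt(i_hp, 0.9)

  # dense oracle (ape) on a small configuration
  set.seed(2)
  co <- matrix(runif(60), 30, 2)
  v <- rnorm(30)
  nn <- knn_neighbors(co, 6)
  Wd <- matrix(0, 30, 30)
  for (i in 1:30) Wd[i, nn$idx[i, ]] <- 1
  i_ape <- ape::Moran.I(v, Wd)$observed   # ape row-standardizes internally
  expect_equal(morans_i(v, co, spatial_neighbors = 6), i_ape,
               tolerance = 1e-10)

  expect_error(morans_i(rep(1, 30), co), "constant")
})

test_that("Moran's I permutation null is centred at -1/(n-1)", {
  g <- as.matrix(expand.grid(x = 1:20, y = 1:20))
  lab <- as.numeric(g[, 1] > 10)
  set.seed(3)
  perm <- replicate(99, morans_i(sample(lab), g, spatial_neighbors = 4))
  expect_lt(abs(mean(perm) - (-1 / (400 - 1))), 3 * sd(perm))
  one <- morans_i(sample(lab), g, spatial_neighbors = 4)
  expect_lt(abs(one - mean(perm)), 4 * sd(perm))
})

test_that("CHAOS has its closed form on the unit grid and is invariant", {
  g <- as.matrix(expand.grid(1:6, 1:6))
  expect_equal(chaos_score(rep(1, 36), g, standardize = FALSE), 1)
  set.seed(4)
  lab <- sample(1:3, 36, replace = TRUE)
  base <- chaos_score(lab, g)
  expect_equal(chaos_score(lab, g + 100), base)       # translation
  expect_equal(chaos_score(lab, g * 7.5), base)       # isotropic rescale
  # contiguous stripes beat the same labels shuffled
  stripes <- rep(1:2, each = 18)
  set.seed(5)
  expect_lt(chaos_score(stripes, g), chaos_score(sample(stripes), g))
  expect_warning(chaos_score(c(rep(1, 35), 2), g), "singleton")
})

test_that("well separated blobs are recovered by every method", {
  set.seed(6)
  P <- rbind(matrix(rnorm(120, 0, 0.5), 60, 2),
             matrix(rnorm(120, 8, 0.5), 60, 2))
  truth <- rep(1:2, each = 60)
  for (m in c("louvain", "leiden", "gmm", "walktrap")) {
    lab <- cluster_embedding(P, method = m, target_k = 2, seed = 7)
    expect_equal(adjusted_rand_index(lab, truth), 1)
  }
})

test_that("resolution search hits the requested cluster number", {
  set.seed(8)
  centers <- matrix(rnorm(16, sd = 10), 8, 2)
  P <- centers[rep(1:8, each = 40), ] + matrix(rnorm(640, sd = 0.5), 320, 2)
  truth <- rep(1:8, each = 40)
  lab <- cluster_embedding(P, "leiden", target_k = 8, seed = 9)
  expect_equal(max(lab), 8L)
  expect_equal(adjusted_rand_index(lab, truth), 1)
})

test_that("degenerate embeddings and walktrap caps are handled", {
  P <- matrix(1, 40, 3)
  lab <- cluster_embedding(P, "louvain", seed = 1)
  expect_equal(max(lab), 1L)
  set.seed(10)
  P2 <- matrix(rnorm(200), 100, 2)
  expect_error(cluster_embedding(P2, "walktrap", walktrap_cap = 50),
               "impractical")
  expect_error(cluster_embedding(P2, "gmm"), "target_k")
  expect_error(cluster_embedding(P2, "louvain", target_k = 1), ">= 2")
})

test_that("parameter sweep emits a tidy reproducible table", {
  sim <- simulate_tissue("stripes", n_cells = 300, seed = 11)
  sc <- as_spatial_counts(sim)
  norm <- normalize_counts(sc)
  tab <- parameter_sweep(norm$X, norm$coords, knn_grid = 3,
                         beta_grid = c(0, 2),
                         methods = c("louvain", "gmm"),
                         truth = sim$domain_labels, p = 8, seed = 12)
  expect_s3_class(tab, "data.frame")
  expect_equal(nrow(tab), 4L)
  expect_named(tab, c("threshold", "beta", "method", "k", "ari",
                      "morans_i", "chaos"))
  expect_true(all(is.finite(tab$ari)))
  tab2 <- parameter_sweep(norm$X, norm$coords, knn_grid = 3,
                          beta_grid = c(0, 2),
                          methods = c("louvain", "gmm"),
                          truth = sim$domain_labels, p = 8, seed = 12)
  expect_identical(tab, tab2)
  # single-cell grids produce one row per method
  tab3 <- parameter_sweep(norm$X, norm$coords, knn_grid = 5, beta_grid = 1,
                          methods = "louvain", p = 8, seed = 12)
  expect_equal(nrow(tab3), 1L)
  expect_true(is.na(tab3$ari))
})
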