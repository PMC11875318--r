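#' Cluster locations on smoothed components
#'
#' Builds a k-nearest-neighbour graph in embedding space — distances are
#' measured on the smoothed components and capture transcriptomic similarity,
#' not the spatial distances used for smoothing — and partitions it with a
#' community-detection algorithm, or fits a Gaussian mixture directly to the
#' scores. When \code{target_k} is set, the graph methods search the
#' resolution parameter by monotone bisection (cluster count grows with
#' resolution) to return the desired number of clusters.
#'
#' @param P n x p matrix of (smoothed) component scores, or an
#'   \code{spca_embedding} (its \code{Pc} is used when present, else
#'   \code{Ps}).
#' @param method one of \code{"louvain"}, \code{"leiden"}, \code{"walktrap"}
#'   (graph community detection) or \code{"gmm"} (model-based Gaussian
#'   mixture, requiring \code{target_k}).
#' @param graph_neighbors neighbours for the embedding-space kNN graph
#'   (default 10; sensible range 5-50 — smaller for cell types, larger for
#'   broad spatial domains).
#' @param target_k desired number of clusters (optional for graph methods).
#' @param resolution_range interval searched by the bisection
#'   (default \code{c(1e-3, 10)}, upper end expanded if needed).
#' @param max_bisect bisection step cap (default 20).
#' @param seed RNG seed for the stochastic partitioners.
#' @param walktrap_cap refuse walktrap above this many locations (its
#'   complexity makes it impractical on large data; default 20000).
#'
#' @return integer vector of labels in \code{1..K} (no empty cluster), with
#'   attributes \code{method}, \code{k}, and \code{resolution} where
#'   applicable.
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_embedding <- function(P, method = c("louvain", "leiden", "gmm",
                                            "walktrap"),
                              graph_neighbors = 10, target_k = NULL,
                              resolution_range = c(1e-3, 10),
                              max_bisect = 20, seed = 1,
                              walktrap_cap = 20000) {
  method <- match.arg(method)
  if (inherits(P, "spca_embedding")) P <- P$Pc %||% P$Ps
  P <- as.matrix(P)
  n <- nrow(P)
  if (!is.null(target_k) && target_k < 2)
    stop("target_k must be >= 2", call. = FALSE)
  if (graph_neighbors < 2 || graph_neighbors >= n)
    stop("graph_neighbors must be in [2, n)", call. = FALSE)

  if (all(apply(P, 2L, stats::sd) == 0)) {
    labels <- rep(1L, n)                 # degenerate: zero-variance embedding
    attr(labels, "method") <- method
    attr(labels, "k") <- 1L
    return(labels)
  }

  if (method == "gmm") {
    if (is.null(target_k)) stop("gmm requires target_k", call. = FALSE)
    set.seed(seed)
    fit <- mclust::Mclust(P, G = target_k, verbose = FALSE)
    if (is.null(fit)) stop("Gaussian mixture fit failed", call. = FALSE)
    labels <- relabel(fit$classification)
    attr(labels, "method") <- "gmm"
    attr(labels, "k") <- max(labels)
    return(labels)
  }

  if (method == "walktrap" && n > walktrap_cap)
    stop("walktrap is impractical above ", walktrap_cap,
         " locations; use louvain or leiden (or raise walktrap_cap)",
         call. = FALSE)

  g <- embedding_knn_graph(P, graph_neighbors)

  if (method == "walktrap") {
    set.seed(seed)
    wt <- igraph::cluster_walktrap(g)
    mem <- if (!is.null(target_k)) {
      tryCatch(igraph::cut_at(wt, no = target_k),
               error = function(e) igraph::membership(wt))
    } else igraph::membership(wt)
    labels <- relabel(mem)
    attr(labels, "method") <- "walktrap"
    attr(labels, "k") <- max(labels)
    return(labels)
  }

  part <- function(res) {
    set.seed(seed)
    if (method == "louvain")
      igraph::membership(igraph::cluster_louvain(g, resolution = res))
    else
      igraph::membership(igraph::cluster_leiden(
        g, objective_function = "modularity", resolution = res,
        n_iterations = 3))
  }

  if (is.null(target_k)) {
    labels <- relabel(part(1))
    attr(labels, "method") <- method
    attr(labels, "k") <- max(labels)
    attr(labels, "resolution") <- 1
    return(labels)
  }

  lo <- resolution_range[1]; hi <- resolution_range[2]
  k_hi <- max(relabel(part(hi)))
  tries <- 0
  while (k_hi < target_k && tries < 6) {   # expand until K reachable
    hi <- hi * 4
    k_hi <- max(relabel(part(hi)))
    tries <- tries + 1
  }
  best <- NULL; best_gap <- Inf; best_res <- NA
  for (step in seq_len(max_bisect)) {
    mid <- sqrt(lo * hi)                   # bisect on log scale
    mem <- relabel(part(mid))
    k <- max(mem)
    gap <- abs(k - target_k)
    if (gap < best_gap) {
      best <- mem; best_gap <- gap; best_res <- mid
    }
    if (k == target_k) break
    if (k < target_k) lo <- mid else hi <- mid
  }
  if (best_gap > 0)
    warning("resolution search could not reach exactly ", target_k,
            " clusters; returning the closest partition (K = ",
            max(best), ")")
  labels <- best
  attr(labels, "method") <- method
  attr(labels, "k") <- max(labels)
  attr(labels, "resolution") <- best_res
  labels
}

# undirected union kNN graph in embedding space
embedding_knn_graph <- function(P, k) {
  nn <- knn_neighbors(P, k)
  n <- nrow(P)
  from <- rep(seq_len(n), times = k)
  to <- as.integer(nn$idx)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::simplify(g)
}

relabel <- function(mem) {
  mem <- as.integer(mem)
  as.integer(match(mem, sort(unique(mem))))
}
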