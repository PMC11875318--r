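#' Simulated tissue geometry
#'
#' Reference-free domain geometries on the unit square, with ground-truth
#' labels for every cell. Two models are provided:
#' \describe{
#'   \item{stripes}{a laminar tissue of \code{n_domains} equal-width vertical
#'     bands; the label is a monotone function of the x coordinate.}
#'   \item{dots}{a complex tissue: one large background domain, six circular
#'     domains with radii drawn from a seeded range and non-overlapping
#'     placement, and one small striped sub-region — eight domains in total.}
#' }
#'
#' @param model \code{"stripes"} or \code{"dots"}.
#' @param n_cells number of cells (default 10000).
#' @param n_domains number of domains (default 8; for \code{dots} exactly 8).
#' @param seed integer seed.
#' @param max_tries placement retries for each dot before erroring.
#' @return list with \code{coords} (n x 2) and \code{domain_labels}
#'   (integers in \code{1..n_domains}).
#' @export
make_geometry <- function(model = c("stripes", "dots"), n_cells = 10000,
                          n_domains = 8, seed = 1, max_tries = 500) {
  model <- match.arg(model)
  if (n_cells < n_domains)
    stop("n_cells must be at least n_domains", call. = FALSE)
  set.seed(as.integer(seed))
  coords <- cbind(x = stats::runif(n_cells), y = stats::runif(n_cells))

  if (model == "stripes") {
    labels <- pmin(floor(coords[, 1] * n_domains) + 1L, n_domains)
    return(list(coords = coords, domain_labels = as.integer(labels)))
  }

  if (n_domains != 8L)
    stop("the dots model is defined for 8 domains", call. = FALSE)
  n_dots <- 6L
  # striped sub-region: two thin bars in the lower-left area (one domain)
  stripe_hit <- function(x, y) {
    bar <- (y >= 0.03 & y <= 0.09) | (y >= 0.15 & y <= 0.21)
    bar & x >= 0.05 & x <= 0.70
  }
  centers <- matrix(NA_real_, n_dots, 2)
  radii <- numeric(n_dots)
  for (d in seq_len(n_dots)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      r <- stats::runif(1, 0.08, 0.15)
      cx <- stats::runif(1, r + 0.02, 1 - r - 0.02)
      cy <- stats::runif(1, max(r + 0.02, 0.26), 1 - r - 0.02)
      ok <- TRUE
      if (d > 1) {
        dd <- sqrt((centers[seq_len(d - 1), 1] - cx)^2 +
                   (centers[seq_len(d - 1), 2] - cy)^2)
        ok <- all(dd > radii[seq_len(d - 1)] + r + 0.03)
      }
      if (ok) {
        centers[d, ] <- c(cx, cy); radii[d] <- r; placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place non-overlapping dots after ", max_tries,
           " tries; reduce dot sizes", call. = FALSE)
  }
  labels <- rep(1L, n_cells)                       # background
  for (d in seq_len(n_dots)) {
    inside <- (coords[, 1] - centers[d, 1])^2 +
              (coords[, 2] - centers[d, 2])^2 <= radii[d]^2
    labels[inside] <- d + 1L
  }
  st <- stripe_hit(coords[, 1], coords[, 2]) & labels == 1L
  labels[st] <- 8L
  list(coords = coords, domain_labels = labels,
       dot_centers = centers, dot_radii = radii)
}

#' Simulate ZINB counts over a tissue geometry
#'
#' Draws a location-by-gene count matrix from per-gene zero-inflated negative
#' binomials. Genes come in three classes: \code{n_low} low-signal and
#' \code{n_high} high-signal genes, each assigned a home domain round-robin,
#' and \code{n_noise} genes with mean \code{mu} everywhere. A signal gene
#' with home domain d is differentially expressed there: its NB mean is
#' \code{mu * (1 + (fold_changes[d] - 1) * multiplier)} inside domain d
#' (multiplier 1 for low-signal, 3 for high-signal genes by default) and
#' \code{mu} elsewhere — domain-specific marker genes, the way reference-free
#' tissue simulators model regional differential expression. Every domain
#' carries a unique fold change, so its markers have a distinctive effect
#' size; \code{fold_changes = 1} everywhere makes all genes exchangeable with
#' noise. Replicate r reseeds with \code{bitwXor(seed, r)}.
#'
#' @param geometry output of [make_geometry()].
#' @param n_low,n_high,n_noise gene counts per class (defaults 50/50/50).
#' @param mu baseline NB mean (default 2).
#' @param zero_prop structural zero probability (default 0.5).
#' @param theta NB dispersion (default 0.5).
#' @param fold_changes per-domain fold changes, one unique value per domain
#'   (default: unit-spaced \code{2, 3, ..., n_domains + 1}, so every region
#'   is differentially expressed).
#' @param low_mult,high_mult multipliers on the fold-change effect for the
#'   two signal classes (defaults 1 and 3).
#' @param seed base seed; \code{replicate} is XOR-folded into it.
#' @param replicate replicate index (default 1).
#' @return an object of class \code{simulated_tissue}: list with
#'   \code{coords}, \code{domain_labels}, \code{counts} (sparse n x m integer
#'   matrix), \code{gene_class}, \code{config}, \code{replicate}.
#' @export
simulate_counts <- function(geometry, n_low = 50, n_high = 50, n_noise = 50,
                            mu = 2, zero_prop = 0.5, theta = 0.5,
                            fold_changes = NULL, low_mult = 1, high_mult = 3,
                            seed = 1, replicate = 1) {
  labels <- geometry$domain_labels
  n <- length(labels)
  n_domains <- max(labels)
  if (is.null(fold_changes))
    fold_changes <- seq(2, length.out = n_domains)
  if (length(fold_changes) != n_domains)
    stop("fold_changes must have one value per domain", call. = FALSE)
  if (any(fold_changes <= 0)) stop("fold_changes must be positive",
                                   call. = FALSE)
  m <- n_low + n_high + n_noise
  gene_class <- rep(c("low", "high", "noise"), c(n_low, n_high, n_noise))
  gene_home <- c(rep_len(seq_len(n_domains), n_low),
                 rep_len(seq_len(n_domains), n_high),
                 rep(NA_integer_, n_noise))
  rep_seed <- bitwXor(as.integer(seed), as.integer(replicate))
  set.seed(rep_seed)
  counts <- matrix(0L, n, m)
  for (g in seq_len(m)) {
    mu_g <- rep(mu, n)
    if (!is.na(gene_home[g])) {
      mult <- if (gene_class[g] == "high") high_mult else low_mult
      home <- labels == gene_home[g]
      mu_g[home] <- mu * (1 + (fold_changes[gene_home[g]] - 1) * mult)
    }
    counts[, g] <- zinb_sample(mu_g, theta, zero_prop, n)
  }
  dimnames(counts) <- list(
    paste0("cell", seq_len(n)),
    paste0(gene_class,
           ifelse(is.na(gene_home), "", paste0("_d", gene_home)), "_",
           stats::ave(seq_len(m), gene_class, FUN = seq_along)))
  structure(
    list(coords = geometry$coords, domain_labels = labels,
         counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix"),
         gene_class = gene_class, gene_home = gene_home,
         config = list(n_cells = n, n_domains = n_domains, n_low = n_low,
                       n_high = n_high, n_noise = n_noise, mu = mu,
                       zero_prop = zero_prop, theta = theta,
                       fold_changes = fold_changes, low_mult = low_mult,
                       high_mult = high_mult, seed = seed),
         replicate = replicate),
    class = "simulated_tissue")
}

#' Simulate a full synthetic tissue
#'
#' Convenience wrapper: [make_geometry()] followed by [simulate_counts()]
#' with the standard study configuration — 10000 cells, 8 domains,
#' 50 low-signal + 50 high-signal + 50 noise genes, ZINB counts with
#' \code{mu = 2}, \code{zero_prop = 0.5}, \code{theta = 0.5}.
#'
#' @inheritParams make_geometry
#' @inheritParams simulate_counts
#' @param ... passed to [simulate_counts()].
#' @return a \code{simulated_tissue}.
#' @export
simulate_tissue <- function(model = c("stripes", "dots"), n_cells = 10000,
                            n_domains = 8, seed = 1, replicate = 1, ...) {
  geo <- make_geometry(model, n_cells = n_cells, n_domains = n_domains,
                       seed = seed)
  sim <- simulate_counts(geo, seed = seed, replicate = replicate, ...)
  sim$model <- match.arg(model)
  sim
}

#' @export
print.simulated_tissue <- function(x, ...) {
  cat("simulated_tissue", if (!is.null(x$model)) paste0(" (", x$model, ")"),
      ": ", nrow(x$counts), " cells x ", ncol(x$counts), " genes, ",
      x$config$n_domains, " domains, replicate ", x$replicate, "\n",
      sep = "")
  invisible(x)
}

#' Convert a simulated tissue to a spatial_counts object
#'
#' @param sim a \code{simulated_tissue}.
#' @return a [spatial_counts()] object ready for [qc_filter()] /
#'   [normalize_counts()].
#' @export
as_spatial_counts <- function(sim) {
  stopifnot(inherits(sim, "simulated_tissue"))
  spatial_counts(sim$counts, sim$coords)
}
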