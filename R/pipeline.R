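#' Run a pipeline stage from a configuration
#'
#' Drives the full workflow from a single configuration (a YAML file or an
#' equivalent nested list) with one section per stage plus \code{input},
#' \code{output} and \code{seed}. Stages: \code{simulate} (synthetic tissue
#' to MTX/TSV), \code{preprocess} (QC filter + normalization),
#' \code{transform} (spatially smoothed PCA), \code{reconstruct}
#' (reduced-rank expression), \code{cluster} (labels + metrics) and
#' \code{sweep} (parameter grid). Unknown configuration keys are rejected,
#' with every problem reported at once; each run writes a
#' \code{manifest.json} (stage, config echo, config hash, seed, package
#' version) next to its outputs, so identical configurations are verifiably
#' identical runs. Partial outputs are removed on failure.
#'
#' @param config path to a YAML file, or a named list.
#' @param stage which stage to run.
#' @return (invisibly) a list with the stage outputs and the manifest.
#' @export
run_pipeline <- function(config,
                         stage = c("simulate", "preprocess", "transform",
                                   "reconstruct", "cluster", "sweep")) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  out_dir <- config$output %||% "."
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  ok <- FALSE
  on.exit(if (!ok && created) unlink(out_dir, recursive = TRUE), add = TRUE)

  result <- switch(stage,
    simulate = {
      sc <- config$simulate %||% list()
      sim <- do.call(simulate_tissue, c(list(seed = seed), sc))
      write_counts_mtx(sim, out_dir)
      list(sim = sim)
    },
    preprocess = {
      raw <- read_input(config)
      pc <- config$preprocess %||% list()
      filt <- do.call(qc_filter, c(list(raw), pc[names(pc) %in%
        names(formals(qc_filter))]))
      norm <- do.call(normalize_counts, c(list(filt), pc[names(pc) %in%
        names(formals(normalize_counts))]))
      write_qc_report(filt, file.path(out_dir, "qc_report.tsv"))
      Matrix::writeMM(methods::as(Matrix::Matrix(norm$X, sparse = TRUE),
                                  "CsparseMatrix"),
                      file.path(out_dir, "normalized.mtx"))
      writeLines(norm$gene_names, file.path(out_dir, "features.tsv"))
      writeLines(norm$location_ids, file.path(out_dir, "barcodes.tsv"))
      utils::write.table(
        data.frame(location_id = norm$location_ids, x = norm$coords[, 1],
                   y = norm$coords[, 2]),
        file.path(out_dir, "coords.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      list(normalized = norm)
    },
    transform = {
      norm <- read_normalized(config)
      tc <- config$transform %||% list()
      emb <- do.call(smoothed_pca,
                     c(list(norm$X, coords = norm$coords, seed = seed),
                       tc[names(tc) %in% names(formals(smoothed_pca))]))
      write_matrix_tsv(emb$Ps, file.path(out_dir, "scores.tsv"),
                       ids = norm$location_ids)
      write_matrix_tsv(emb$W, file.path(out_dir, "loadings.tsv"),
                       ids = norm$gene_names)
      list(embedding = emb)
    },
    reconstruct = {
      norm <- read_normalized(config)
      tc <- config$transform %||% list()
      rc <- config$reconstruct %||% list()
      emb <- do.call(smoothed_pca,
                     c(list(norm$X, coords = norm$coords, seed = seed),
                       tc[names(tc) %in% names(formals(smoothed_pca))]))
      rec <- do.call(reconstruct_expression,
                     c(list(norm$X, emb),
                       rc[names(rc) %in%
                          names(formals(reconstruct_expression))]))
      Matrix::writeMM(methods::as(Matrix::Matrix(rec$Xr, sparse = TRUE),
                                  "CsparseMatrix"),
                      file.path(out_dir, "reconstructed.mtx"))
      utils::write.table(rec$audit, file.path(out_dir, "audit.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(reconstruction = rec)
    },
    cluster = {
      norm <- read_normalized(config)
      tc <- config$transform %||% list()
      cc <- config$cluster %||% list()
      emb <- do.call(smoothed_pca,
                     c(list(norm$X, coords = norm$coords, seed = seed),
                       tc[names(tc) %in% names(formals(smoothed_pca))]))
      labels <- do.call(cluster_embedding,
                        c(list(emb$Ps, seed = seed),
                          cc[names(cc) %in%
                             names(formals(cluster_embedding))]))
      utils::write.table(
        data.frame(location_id = norm$location_ids,
                   cluster = as.integer(labels)),
        file.path(out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      list(labels = labels)
    },
    sweep = {
      norm <- read_normalized(config)
      sc <- config$sweep %||% list()
      tab <- do.call(parameter_sweep,
                     c(list(norm$X, coords = norm$coords, seed = seed),
                       sc[names(sc) %in% names(formals(parameter_sweep))]))
      utils::write.table(tab, file.path(out_dir, "sweep.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(sweep = tab)
    })

  manifest <- list(stage = stage, seed = seed, config = config,
                   config_hash = config_hash(config),
                   package_version = as.character(
                     utils::packageVersion("smoothpca")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(c(result, list(manifest = manifest)))
}

read_input <- function(config) {
  inp <- config$input
  if (is.null(inp)) stop("config$input is required for this stage",
                         call. = FALSE)
  if (dir.exists(inp)) {
    read_counts_mtx(file.path(inp, "matrix.mtx"),
                    file.path(inp, "features.tsv"),
                    file.path(inp, "barcodes.tsv"),
                    file.path(inp, "coords.tsv"))
  } else {
    read_counts_csv(inp, coords = config$coords)
  }
}

read_normalized <- function(config) {
  inp <- config$input
  if (is.null(inp) || !dir.exists(inp))
    stop("config$input must be a directory holding normalized.mtx or ",
         "matrix.mtx outputs", call. = FALSE)
  mtx <- if (file.exists(file.path(inp, "normalized.mtx")))
    file.path(inp, "normalized.mtx") else file.path(inp, "matrix.mtx")
  M <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- readLines(file.path(inp, "features.tsv"))
  ids <- readLines(file.path(inp, "barcodes.tsv"))
  co <- utils::read.delim(file.path(inp, "coords.tsv"),
                          stringsAsFactors = FALSE)
  rownames(M) <- ids; colnames(M) <- genes
  list(X = M, coords = as.matrix(co[, c("x", "y")]), gene_names = genes,
       location_ids = ids)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

validate_config <- function(config) {
  known_top <- c("input", "coords", "output", "seed", "verbosity",
                 "simulate", "preprocess", "transform", "reconstruct",
                 "cluster", "sweep")
  known_sub <- list(
    simulate = c(names(formals(simulate_tissue)),
                 names(formals(simulate_counts))),
    preprocess = c(names(formals(qc_filter)),
                   names(formals(normalize_counts))),
    transform = names(formals(smoothed_pca)),
    reconstruct = names(formals(reconstruct_expression)),
    cluster = names(formals(cluster_embedding)),
    sweep = names(formals(parameter_sweep)))
  problems <- character(0)
  bad <- setdiff(names(config), known_top)
  if (length(bad))
    problems <- c(problems, paste0("unknown top-level key(s): ",
                                   paste(bad, collapse = ", ")))
  for (sec in intersect(names(config), names(known_sub))) {
    bad <- setdiff(names(config[[sec]]), known_sub[[sec]])
    if (length(bad))
      problems <- c(problems, paste0("unknown key(s) in '", sec, "': ",
                                     paste(bad, collapse = ", ")))
  }
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(TRUE)
}
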