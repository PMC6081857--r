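#' Compute the paired distance matrices for a clustering run
#'
#' Restricts the analysis to the working gene set — the intersection of
#' expressed and annotated genes (the biology-based distance is undefined for
#' unannotated genes) — then computes the expression-based (Pearson) and
#' biology-based (Wang) distance matrices over it. Annotations are first
#' filtered to one GO namespace.
#'
#' @param X A row-normalised [expression_matrix()] (standardised here if
#'   not already).
#' @param dag A [go_dag()].
#' @param ann A [gene_annotation()].
#' @param namespace GO namespace feeding the biology-based distance
#'   (default `"biological_process"`).
#' @param combine Term-similarity aggregation rule (see
#'   [gene_functional_similarity()]).
#' @return List with `D_EB`, `D_BB` and `genes` (the working gene set, whose
#'   size is reported via `message()`).
#' @export
compute_distances <- function(X, dag, ann,
                              namespace = "biological_process",
                              combine = "bma") {
  if (!isTRUE(attr(X, "normalized"))) X <- normalize_rows(X)
  ann <- filter_namespace(ann, dag, namespace)
  genes <- intersect(rownames(X), names(ann))
  if (length(genes) < 3L)
    stop("fewer than 3 genes in the expressed-and-annotated intersection")
  message("working gene set: ", length(genes),
          " genes (expressed and annotated)")
  Xs <- expression_matrix(unclass(X)[genes, , drop = FALSE], normalized = TRUE)
  list(D_EB = expression_distance(Xs),
       D_BB = biological_distance(ann, dag, genes, combine = combine),
       genes = genes)
}

#' Run the full multi-objective clustering pipeline
#'
#' Evolves one Pareto front per requested cluster count `K`, selects the
#' single best solution across all fronts by mean silhouette under the
#' expression-based distance, and optionally writes run artifacts
#' (`front.json`, `partition.tsv`, `summary.json`, `run.log`).
#'
#' @param D_EB,D_BB [distance_matrix()] objects over the same gene universe.
#' @param ks Integer vector of cluster counts to try (default `c(4, 5, 6)`).
#' @param seed Integer seed; each `K`'s run is seeded with it.
#' @param out_dir Optional output directory for artifacts.
#' @param ... Further arguments to [run_config()] (index, local_search,
#'   pop_size, ...).
#' @return List of class `moc_run` with `fronts` (one `pareto_front` per K),
#'   `best` (list: `K`, selection from [select_single_solution()]),
#'   `hypervolumes` (per K, under a normalisation shared across Ks) and the
#'   effective `config`s.
#' @export
moc_run <- function(D_EB, D_BB, ks = c(4L, 5L, 6L), seed = 1L,
                    out_dir = NULL, ...) {
  if (!identical(rownames(D_EB), rownames(D_BB)))
    stop("inconsistent gene universes: ",
         paste(union(setdiff(rownames(D_EB), rownames(D_BB)),
                     setdiff(rownames(D_BB), rownames(D_EB))),
               collapse = ", "))
  log_lines <- character()
  log_add <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  fronts <- list()
  configs <- list()
  for (K in ks) {
    cfg <- run_config(K = K, seed = seed, ...)
    log_add("run K=", K, ": ",
            paste(names(unclass(cfg)), unlist(cfg), sep = "=", collapse = " "))
    fr <- evolve(cfg, D_EB, D_BB)
    log_add("  -> ", length(fr$chromosomes), " solution(s), ",
            fr$generations_run, " generation(s), stop: ", fr$stop_reason)
    fronts[[as.character(K)]] <- fr
    configs[[as.character(K)]] <- cfg
  }
  selections <- lapply(fronts, select_single_solution, D_EB = D_EB)
  sils <- vapply(selections, `[[`, numeric(1L), "silhouette")
  best_i <- which.max(sils)
  best_K <- as.integer(names(fronts)[best_i])
  log_add("best K by silhouette: ", best_K,
          " (S = ", format(sils[best_i], digits = 4L), ")")
  hv <- hypervolume_compare(lapply(fronts, `[[`, "objectives"),
                            fronts[[1L]]$orientation)
  names(hv) <- names(fronts)
  res <- structure(list(fronts = fronts, selections = selections,
                        best = list(K = best_K,
                                    selection = selections[[best_i]]),
                        hypervolumes = hv, configs = configs,
                        seed = seed, log = log_lines),
                   class = "moc_run")
  if (!is.null(out_dir)) write_run_artifacts(res, out_dir)
  res
}

write_run_artifacts <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  best <- res$best
  fr <- res$fronts[[as.character(best$K)]]
  front_json <- list(
    index = fr$index,
    orientation = fr$orientation,
    gene_ids = fr$gene_ids,
    solutions = lapply(seq_along(fr$chromosomes), function(i) list(
      medoids = fr$chromosomes[[i]],
      objectives = unname(fr$objectives[i, ]),
      rank = 1L)))
  jsonlite::write_json(front_json, file.path(out_dir, "front.json"),
                       auto_unbox = TRUE, digits = NA)
  part <- best$selection$partition
  utils::write.table(
    data.frame(gene = fr$gene_ids, cluster = part$assignment),
    file.path(out_dir, "partition.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  summary_json <- list(
    seed = res$seed,
    best_K = best$K,
    silhouette = best$selection$silhouette,
    medoids = best$selection$chromosome,
    hypervolumes = as.list(res$hypervolumes),
    config = unclass(res$configs[[as.character(best$K)]]))
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(res$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Read a key = value run-configuration file
#'
#' Lines of the form `key = value` (comments with `#`) mirroring the
#' [run_config()] fields; values are coerced to the default's type.
#'
#' @param path Path to the configuration file.
#' @param K Cluster count (required by [run_config()], may also appear in the
#'   file).
#' @return A [run_config()].
#' @export
read_run_config <- function(path, K = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- lapply(strsplit(lines, "=", fixed = TRUE), trimws)
  args <- stats::setNames(lapply(kv, function(x) {
    v <- x[[2L]]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }), vapply(kv, `[[`, character(1L), 1L))
  if (!is.null(K)) args$K <- K
  do.call(run_config, args)
}

#' @export
print.moc_run <- function(x, ...) {
  cat("multi-objective clustering run over K in {",
      paste(names(x$fronts), collapse = ", "), "}\n", sep = "")
  cat("best K:", x$best$K, " silhouette:",
      format(x$best$selection$silhouette, digits = 4L), "\n")
  invisible(x)
}
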