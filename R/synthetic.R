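#' Specification of a synthetic planted-cluster dataset
#'
#' Defines the study conditions for the seeded fixture generator: planted
#' co-expressed gene clusters (sinusoid template profiles with
#' cluster-specific phase plus Gaussian noise, rows then standardised) and a
#' concordant toy ontology in which each planted cluster owns a subtree of
#' terms that annotates its genes.
#'
#' @param n_genes Number of genes (default 120).
#' @param n_samples Number of samples/time points (default 8).
#' @param k_planted Number of planted clusters, `>= 2` (default 4).
#' @param noise_sd Gaussian noise standard deviation on expression
#'   (default 0.3).
#' @param concordance Probability that a gene is annotated from its own
#'   cluster's term pool rather than a random other pool (default 0.9).
#' @param dag_depth Depth of each cluster's term chain under the root
#'   (default 3).
#' @param terms_per_cluster Terms in each cluster's subtree (default 6).
#' @param seed Integer seed fixing all randomness (default 7).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 120L, n_samples = 8L, k_planted = 4L,
                           noise_sd = 0.3, concordance = 0.9,
                           dag_depth = 3L, terms_per_cluster = 6L,
                           seed = 7L) {
  stopifnot(k_planted >= 2L, n_genes >= k_planted,
            concordance >= 0, concordance <= 1,
            dag_depth >= 1L, terms_per_cluster >= max(3L, dag_depth))
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 k_planted = as.integer(k_planted),
                 noise_sd = noise_sd, concordance = concordance,
                 dag_depth = as.integer(dag_depth),
                 terms_per_cluster = as.integer(terms_per_cluster),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

planted_labels <- function(spec) {
  sort(rep_len(seq_len(spec$k_planted), spec$n_genes))
}

generate_expression_impl <- function(spec) {
  labels <- planted_labels(spec)
  t_grid <- seq_len(spec$n_samples) - 1L
  templates <- t(vapply(seq_len(spec$k_planted), function(c)
    sin(2 * pi * t_grid / spec$n_samples + 2 * pi * (c - 1) / spec$k_planted),
    numeric(spec$n_samples)))
  X <- templates[labels, , drop = FALSE] +
    matrix(stats::rnorm(spec$n_genes * spec$n_samples, 0, spec$noise_sd),
           spec$n_genes, spec$n_samples)
  rownames(X) <- sprintf("g%04d", seq_len(spec$n_genes))
  colnames(X) <- sprintf("s%d", seq_len(spec$n_samples))
  X <- suppressWarnings(normalize_rows(expression_matrix(X)))
  labels <- labels[match(rownames(X), sprintf("g%04d", seq_len(spec$n_genes)))]
  list(X = X, labels = labels)
}

#' Generate a planted-cluster expression matrix
#'
#' Each planted cluster has a distinct smooth sinusoid template (phase-shifted
#' by cluster), each gene is its cluster's template plus `N(0, noise_sd)`
#' noise, and rows are standardised to mean 0 / variance 1. With zero noise,
#' genes of the same cluster have identical standardised profiles.
#'
#' @param spec A [synthetic_spec()]; its `seed` fixes the output.
#' @return List with `X` (an [expression_matrix()]) and `labels` (planted
#'   cluster of each retained gene).
#' @export
generate_expression <- function(spec) {
  set.seed(spec$seed)
  generate_expression_impl(spec)
}

generate_dag_impl <- function(spec, labels) {
  k <- spec$k_planted
  tpc <- spec$terms_per_cluster
  root <- "T:0000"
  terms <- root
  child <- character(); parent <- character(); type <- character()
  pools <- vector("list", k)
  for (c in seq_len(k)) {
    ids <- sprintf("T:%d%03d", c, seq_len(tpc))
    terms <- c(terms, ids)
    # chain of dag_depth terms under the root forms the subtree spine
    spine <- ids[seq_len(spec$dag_depth)]
    child <- c(child, spine[1L]); parent <- c(parent, root)
    type <- c(type, "is_a")
    if (spec$dag_depth > 1L) {
      for (d in 2:spec$dag_depth) {
        child <- c(child, spine[d]); parent <- c(parent, spine[d - 1L])
        type <- c(type, "is_a")
      }
    }
    # remaining terms hang off random spine/subtree nodes, mixing edge types
    rest <- setdiff(ids, spine)
    attached <- spine
    for (t in rest) {
      p <- if (length(attached) == 1L) attached else sample(attached, 1L)
      child <- c(child, t); parent <- c(parent, p)
      type <- c(type, if (stats::runif(1L) < 0.7) "is_a" else "part_of")
      attached <- c(attached, t)
    }
    pools[[c]] <- ids
  }
  ns <- stats::setNames(rep("biological_process", length(terms)), terms)
  dag <- go_dag(terms, data.frame(child = child, parent = parent, type = type,
                                  stringsAsFactors = FALSE), namespace = ns)
  genes <- sprintf("g%04d", seq_along(labels))
  ann <- vector("list", length(genes))
  names(ann) <- genes
  for (i in seq_along(genes)) {
    own <- stats::runif(1L) < spec$concordance
    # misannotated genes draw a subtree uniformly over all clusters, so at
    # concordance 0 within- and between-cluster term pools are exchangeable
    # and the annotations carry no cluster signal
    pool_id <- if (own) labels[i] else sample.int(k, 1L)
    n_terms <- sample(1:3, 1L)
    ann[[i]] <- sample(pools[[pool_id]], min(n_terms, tpc))
  }
  list(dag = dag, ann = gene_annotation(ann, dag), pools = pools)
}

#' Generate a toy ontology and concordant gene annotations
#'
#' Builds a rooted DAG with one subtree of `terms_per_cluster` terms per
#' planted cluster (an `is_a` spine of depth `dag_depth` plus randomly
#' attached leaves mixing `is_a`/`part_of` edges) and annotates each gene
#' with 1-3 terms from its own cluster's subtree with probability
#' `concordance`, otherwise from a subtree chosen uniformly over all
#' clusters (which makes zero concordance carry no cluster signal at all).
#'
#' @param spec A [synthetic_spec()].
#' @param labels Planted labels from [generate_expression()].
#' @return List with `dag` (a [go_dag()]) and `ann` (a [gene_annotation()]).
#' @export
generate_dag_and_annotations <- function(spec, labels) {
  set.seed(spec$seed)
  generate_dag_impl(spec, labels)[c("dag", "ann")]
}

#' Generate a complete synthetic dataset
#'
#' Runs the expression and ontology/annotation generators off a single seeded
#' random stream, so the whole fixture is reproducible from one integer.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `X`, `labels`, `dag`, `ann` and the `spec`.
#' @export
simulate_dataset <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  ex <- generate_expression_impl(spec)
  da <- generate_dag_impl(spec, ex$labels)
  list(X = ex$X, labels = ex$labels, dag = da$dag, ann = da$ann, spec = spec)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `expression.tsv`, `toy.obo`, `annotations.tsv` (two-column
#' gene/term) and `labels.tsv` into `dir`.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_tsv(sim$X, file.path(dir, "expression.tsv"))
  write_obo(sim$dag, file.path(dir, "toy.obo"))
  ann_df <- data.frame(
    gene = rep(names(sim$ann), lengths(sim$ann)),
    term = unlist(sim$ann, use.names = FALSE))
  utils::write.table(ann_df, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(gene = rownames(sim$X), label = sim$labels),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
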