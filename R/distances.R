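#' Expression-based distance matrix
#'
#' Pairwise distance `1 - rho(x, y)` where `rho` is the Pearson correlation of
#' two gene profiles, giving values in `[0, 2]`: 0 for perfectly correlated
#' profiles, 2 for perfectly anti-correlated ones.
#'
#' @param X A row-standardised [expression_matrix()] (see [normalize_rows()]).
#' @return A [distance_matrix()] tagged `"EB"`.
#' @export
expression_distance <- function(X) {
  if (!isTRUE(attr(X, "normalized")))
    stop("expression matrix must be row-normalized before computing distances")
  if (ncol(X) < 3L)
    warning("fewer than 3 samples: Pearson correlation is poorly determined")
  v <- apply(X, 1L, stats::var)
  if (any(v == 0)) stop("zero-variance row(s) present: ",
                        paste(rownames(X)[v == 0], collapse = ", "))
  D <- 1 - stats::cor(t(unclass(X)))
  D <- (D + t(D)) / 2
  D[D < 0] <- 0          # clamp -eps from floating point
  D[D > 2] <- 2
  diag(D) <- 0
  distance_matrix(D, source = "EB")
}

# S-values of a term's ancestor closure: S(t) = 1 at the term itself, and for
# each ancestor a, S(a) = max over edges (c -> a) inside the closure of
# w(c -> a) * S(c), with is_a weight 0.8 and part_of weight 0.6.
wang_svalues <- function(dag, term) {
  if (!(term %in% dag$terms)) stop("unknown term: ", term)
  s <- c(1); names(s) <- term
  queue <- term
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    for (i in dag$parents[[t]]) {
      p <- dag$edges$parent[i]
      cand <- dag$edges$weight[i] * s[[t]]
      if (is.na(s[p]) || cand > s[[p]]) {
        s[p] <- cand
        queue <- c(queue, p)
      }
    }
  }
  s
}

#' Wang semantic similarity of two ontology terms
#'
#' Propagates semantic-contribution S-values through the ancestor closure of
#' each term (`is_a` edges contribute a factor 0.8, `part_of` 0.6, taking the
#' maximum over paths) and contrasts the shared ancestors against the total
#' semantic value of each term:
#' \deqn{WS(A,B) = \frac{\sum_{t \in T_A \cap T_B} (S_A(t) + S_B(t))}
#'                      {SV(A) + SV(B)}}
#'
#' @param dag A [go_dag()].
#' @param t1,t2 Term IDs present in `dag`.
#' @return Similarity in `[0, 1]`; 1 iff the terms coincide, 0 when their
#'   ancestor closures are disjoint.
#' @export
wang_term_similarity <- function(dag, t1, t2) {
  s1 <- wang_svalues(dag, t1)
  s2 <- wang_svalues(dag, t2)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0L) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

# Pairwise term-similarity matrix over a term set, with memoized S-values.
term_similarity_matrix <- function(dag, terms) {
  terms <- unique(terms)
  sv <- lapply(terms, function(t) wang_svalues(dag, t))
  names(sv) <- terms
  tot <- vapply(sv, sum, numeric(1L))
  m <- diag(1, length(terms))
  dimnames(m) <- list(terms, terms)
  if (length(terms) > 1L) {
    for (i in seq_len(length(terms) - 1L)) {
      for (j in (i + 1L):length(terms)) {
        common <- intersect(names(sv[[i]]), names(sv[[j]]))
        w <- if (length(common)) {
          sum(sv[[i]][common] + sv[[j]][common]) / (tot[[i]] + tot[[j]])
        } else 0
        m[i, j] <- m[j, i] <- w
      }
    }
  }
  m
}

combine_term_sims <- function(sim_block, combine) {
  switch(combine,
         bma = (sum(apply(sim_block, 1L, max)) +
                  sum(apply(sim_block, 2L, max))) /
           (nrow(sim_block) + ncol(sim_block)),
         max = max(sim_block),
         avg = mean(sim_block))
}

#' Functional similarity of two annotated genes
#'
#' Aggregates the Wang similarities of all term pairs between the two genes'
#' annotation sets. The default best-match average (BMA) averages, for each
#' term, its best match in the other gene's set.
#'
#' @param gA,gB Gene IDs present in `ann`.
#' @param ann A [gene_annotation()].
#' @param dag A [go_dag()].
#' @param combine Aggregation rule: `"bma"` (default), `"max"` or `"avg"`.
#' @return Similarity in `[0, 1]`.
#' @export
gene_functional_similarity <- function(gA, gB, ann, dag,
                                       combine = c("bma", "max", "avg")) {
  combine <- match.arg(combine)
  if (is.null(ann[[gA]]) || is.null(ann[[gB]]))
    stop("both genes must be annotated: ",
         paste(setdiff(c(gA, gB), names(ann)), collapse = ", "))
  terms <- unique(c(ann[[gA]], ann[[gB]]))
  sm <- term_similarity_matrix(dag, terms)
  combine_term_sims(sm[ann[[gA]], ann[[gB]], drop = FALSE], combine)
}

#' Biology-based distance matrix
#'
#' Entry `(x, y)` is `1 - WS(G_x, G_y)` where `WS` is the aggregated Wang
#' functional similarity of the two genes' annotation sets, giving values in
#' `[0, 1]`. Term-pair similarities are computed once over the union of all
#' used terms; the matrix is filled row-major over the supplied gene order, so
#' results do not depend on construction order.
#'
#' @param ann A [gene_annotation()].
#' @param dag A [go_dag()].
#' @param genes Ordered gene IDs to include; all must be annotated.
#' @param combine Term aggregation rule passed to the gene-level similarity.
#' @return A [distance_matrix()] tagged `"BB"`.
#' @export
biological_distance <- function(ann, dag, genes = names(ann),
                                combine = c("bma", "max", "avg")) {
  combine <- match.arg(combine)
  missing_ann <- setdiff(genes, names(ann))
  if (length(missing_ann))
    stop("gene(s) without annotation: ", paste(missing_ann, collapse = ", "))
  used_terms <- unique(unlist(ann[genes]))
  sm <- term_similarity_matrix(dag, used_terms)
  n <- length(genes)
  D <- matrix(0, n, n, dimnames = list(genes, genes))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      ti <- ann[[genes[i]]]
      for (j in (i + 1L):n) {
        ws <- combine_term_sims(sm[ti, ann[[genes[j]]], drop = FALSE], combine)
        D[i, j] <- D[j, i] <- 1 - ws
      }
    }
  }
  D[D < 0] <- 0
  distance_matrix(D, source = "BB")
}
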