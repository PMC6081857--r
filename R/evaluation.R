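#' Min-max normalise a front into the unit square
#'
#' Maximised coordinates are negated first, then each coordinate is min-max
#' scaled to `[0, 1]` over the supplied point set, so `(0, 0)` is the ideal
#' corner and `(1, 1)` the reference point for hypervolume. A coordinate with
#' zero range maps to 0. When several fronts are compared, normalise them
#' jointly (pass the union, or shared `bounds`) so the reference point is
#' common.
#'
#' @param points Numeric matrix of objective vectors (one row per solution).
#' @param orientations Character vector, `"min"`/`"max"` per coordinate.
#' @param bounds Optional list with `lo` and `hi` numeric vectors giving the
#'   normalisation range per (minimised) coordinate; defaults to the range of
#'   `points`.
#' @return Matrix of the same shape with entries in `[0, 1]`.
#' @export
normalize_front <- function(points, orientations = c("min", "min"),
                            bounds = NULL) {
  points <- rbind(points)
  stopifnot(ncol(points) == length(orientations))
  s <- ifelse(orientations == "max", -1, 1)
  m <- sweep(points, 2L, s, "*")
  finite_rng <- function(x) if (any(is.finite(x))) range(x[is.finite(x)])
  else c(0, 0)
  lo <- if (is.null(bounds)) apply(m, 2L, function(x) finite_rng(x)[1L])
  else bounds$lo
  hi <- if (is.null(bounds)) apply(m, 2L, function(x) finite_rng(x)[2L])
  else bounds$hi
  rng <- hi - lo
  out <- m
  for (j in seq_len(ncol(m))) {
    out[, j] <- if (rng[j] > 0) (m[, j] - lo[j]) / rng[j] else 0
    # degenerate solutions with an infinite index value sit on the worst
    # boundary of the unit square
    out[!is.finite(out[, j]), j] <- 1
    out[, j] <- pmin(pmax(out[, j], 0), 1)
  }
  out
}

#' Two-dimensional hypervolume
#'
#' Area of the union of the rectangles `[x, 1] x [y, 1]` spanned by each
#' point and the reference point `(1, 1)`; dominated points contribute
#' nothing. Larger is better.
#'
#' @param points Numeric matrix of normalised minimised points in the unit
#'   square (one row per point); may be empty.
#' @param reference Reference point, default `c(1, 1)`.
#' @return Scalar in `[0, 1]` for the default reference.
#' @export
hypervolume_2d <- function(points, reference = c(1, 1)) {
  if (is.null(points) || length(points) == 0L) return(0)
  points <- rbind(points)
  stopifnot(ncol(points) == 2L)
  if (any(points < 0 - 1e-12) || any(points > rep(reference, each = nrow(points)) + 1e-12))
    stop("points must lie within [0, reference] in both coordinates")
  f1 <- fast_nondominated_sort(points)[[1L]]
  p <- points[f1, , drop = FALSE]
  p <- unique(p)
  p <- p[order(p[, 1L], p[, 2L]), , drop = FALSE]
  area <- 0
  prev_y <- reference[2L]
  for (i in seq_len(nrow(p))) {
    area <- area + (reference[1L] - p[i, 1L]) * (prev_y - p[i, 2L])
    prev_y <- p[i, 2L]
  }
  area
}

#' Hypervolumes of several fronts under a common normalisation
#'
#' Normalises the union of all supplied fronts jointly (so `(1, 1)` is a
#' shared reference point) and returns each front's hypervolume.
#'
#' @param fronts List of numeric matrices of raw objective vectors.
#' @param orientations `"min"`/`"max"` per coordinate.
#' @return Numeric vector of hypervolumes, one per front.
#' @export
hypervolume_compare <- function(fronts, orientations = c("min", "min")) {
  all_pts <- do.call(rbind, fronts)
  s <- ifelse(orientations == "max", -1, 1)
  m <- sweep(all_pts, 2L, s, "*")
  bounds <- list(lo = apply(m, 2L, min), hi = apply(m, 2L, max))
  vapply(fronts, function(f)
    hypervolume_2d(normalize_front(f, orientations, bounds)), numeric(1L))
}

#' Select a single solution from a front by silhouette
#'
#' Computes the mean silhouette of every front member's nearest-medoid
#' partition under the expression-based distance and returns the argmax; ties
#' are broken by the lowest first (minimised) objective, then lexicographic
#' chromosome order.
#'
#' @param front A `pareto_front` from [evolve()].
#' @param D_EB Expression-based [distance_matrix()] (the same gene universe
#'   as the run).
#' @return List with `chromosome`, `silhouette`, `partition` (a `partition`
#'   under `D_EB`), `objectives` (raw) and `which` (index into the front).
#' @export
select_single_solution <- function(front, D_EB) {
  stopifnot(inherits(front, "pareto_front"))
  m <- length(front$chromosomes)
  if (m == 0L) stop("empty front")
  sil <- vapply(front$chromosomes, function(ch)
    silhouette_index(D_EB, assign_to_medoids(D_EB, ch)), numeric(1L))
  s <- ifelse(front$orientation == "max", -1, 1)
  min_obj1 <- front$objectives[, 1L] * s[1L]
  lex <- integer(m)
  lex[chrom_lex_order(front$chromosomes)] <- seq_len(m)
  ord <- order(-sil, min_obj1, lex)
  best <- ord[1L]
  list(chromosome = front$chromosomes[[best]],
       silhouette = sil[best],
       partition = assign_to_medoids(D_EB, front$chromosomes[[best]]),
       objectives = front$objectives[best, ],
       which = best)
}

#' Front summary: normalised points, hypervolume, selected solution
#'
#' @param front A `pareto_front`.
#' @param D_EB Expression-based [distance_matrix()] for silhouette selection.
#' @param bounds Optional shared normalisation bounds (see
#'   [normalize_front()]).
#' @return List with `points` (normalised), `hypervolume`, `selected`.
#' @export
evaluate_front <- function(front, D_EB, bounds = NULL) {
  pts <- normalize_front(front$objectives, front$orientation, bounds)
  list(points = pts,
       hypervolume = hypervolume_2d(pts),
       selected = select_single_solution(front, D_EB))
}

#' Friedman rank test over a score table
#'
#' Ranks the algorithms within each dataset (rank 1 = highest score) and
#' tests whether the mean ranks differ, using the tie-corrected chi-square
#' statistic on `k - 1` degrees of freedom. Mid-ranks are used for tied
#' scores when computing the statistic; the reported rank matrix follows
#' `tie_method` (`"midrank"` default, or `"min"`, which assigns tied scores
#' the smallest rank of their group as some published tables do).
#'
#' @param scores Numeric matrix or data frame, datasets x algorithms, higher
#'   scores better; no missing cells.
#' @return List with `statistic`, `p_value`, `mean_ranks` (per algorithm,
#'   from the `tie_method` ranks), `ranks` (the rank matrix) and `df`.
#' @param tie_method `"midrank"` or `"min"`.
#' @export
friedman_test <- function(scores, tie_method = c("midrank", "min")) {
  tie_method <- match.arg(tie_method)
  scores <- as.matrix(scores)
  stopifnot(is.numeric(scores), !anyNA(scores),
            nrow(scores) >= 2L, ncol(scores) >= 2L)
  n <- nrow(scores); k <- ncol(scores)
  rank_row <- function(x, method) rank(-x, ties.method = method)
  mid <- t(apply(scores, 1L, rank_row, method = "average"))
  shown <- if (tie_method == "midrank") mid
  else t(apply(scores, 1L, rank_row, method = "min"))
  colnames(mid) <- colnames(shown) <- colnames(scores)
  tie_term <- sum(apply(scores, 1L, function(x) {
    tt <- table(x)
    sum(tt^3 - tt)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  stat <- if (denom > 0)
    12 * sum((colSums(mid) - n * (k + 1) / 2)^2) / denom else 0
  p <- if (denom > 0) stats::pchisq(stat, df = k - 1, lower.tail = FALSE) else 1
  list(statistic = stat, p_value = p,
       mean_ranks = colMeans(shown), ranks = shown, df = k - 1L)
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability of observing `k` or more genes annotated with a
#' term in a cluster of size `n`, when `f` of the `g` genes in the genome
#' carry the term:
#' \deqn{p = 1 - \sum_{i=0}^{k-1} \binom{f}{i}\binom{g-f}{n-i} / \binom{g}{n}}
#' Evaluated through the exact hypergeometric tail, which is computed in
#' log-space and is stable for large counts.
#'
#' @param k Genes in the cluster carrying the term.
#' @param n Cluster size.
#' @param f Genes in the genome carrying the term.
#' @param g Genome size.
#' @return p-value in `[0, 1]`; 1 when `k = 0`, 0 when `k > min(n, f)`.
#' @export
enrichment_pvalue <- function(k, n, f, g) {
  stopifnot(k >= 0, n >= k, g >= n, f >= 0, g >= f)
  if (k == 0) return(1)
  stats::phyper(k - 1, m = f, n = g - f, k = n, lower.tail = FALSE)
}
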