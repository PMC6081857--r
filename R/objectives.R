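#' Assign every gene to its nearest medoid
#'
#' Medoids are canonicalised in ascending gene-index order before assignment,
#' so the partition depends only on the medoid set; a gene equidistant to two
#' medoids goes to the lower-indexed one. Every medoid is at distance 0 from
#' itself, hence belongs to its own cluster and no cluster is empty.
#'
#' @param D A [distance_matrix()].
#' @param medoids Integer vector of `K` distinct gene indices (1-based),
#'   `2 <= K < n`.
#' @return A list of class `partition` with `assignment` (gene -> cluster in
#'   `1..K`), `medoids` (sorted) and the distance `source` tag.
#' @export
assign_to_medoids <- function(D, medoids) {
  n <- nrow(D)
  K <- length(medoids)
  if (anyDuplicated(medoids)) stop("medoids must be distinct")
  if (K < 2L || K >= n) stop("need 2 <= K < n")
  med <- sort(as.integer(medoids))
  dm <- unclass(D)[, med, drop = FALSE]           # n x K
  assignment <- max.col(-dm, ties.method = "first")
  structure(list(assignment = assignment, medoids = med,
                 source = attr(D, "source")),
            class = "partition")
}

# distance of each gene to its assigned medoid
member_distances <- function(D, part) {
  unclass(D)[cbind(seq_along(part$assignment), part$medoids[part$assignment])]
}

#' Xie-Beni index for a medoid clustering
#'
#' Crisp medoid form: the sum of squared distances of genes to their assigned
#' medoid, divided by `n` times the minimum squared inter-medoid distance.
#' Lower is better. The `variant = "allpairs"` reading sums squared distances
#' of every gene to every medoid instead.
#'
#' @param D A [distance_matrix()].
#' @param medoids Integer vector of K distinct gene indices.
#' @param variant `"crisp"` (default) or `"allpairs"`.
#' @return Non-negative scalar (minimisation objective).
#' @export
xie_beni <- function(D, medoids, variant = c("crisp", "allpairs")) {
  variant <- match.arg(variant)
  part <- assign_to_medoids(D, medoids)
  med <- part$medoids
  n <- nrow(D)
  dmm <- unclass(D)[med, med, drop = FALSE]
  sep2 <- min(dmm[upper.tri(dmm)]^2)
  if (sep2 == 0) stop("two medoids at distance 0: Xie-Beni undefined")
  num <- if (variant == "crisp") sum(member_distances(D, part)^2)
  else sum(unclass(D)[, med]^2)
  num / (n * sep2)
}

#' Overall cluster deviation
#'
#' Summed distance from every gene to its assigned cluster medoid; lower is
#' better (compactness).
#'
#' @inheritParams xie_beni
#' @return Non-negative scalar (minimisation objective).
#' @export
overall_deviation <- function(D, medoids) {
  part <- assign_to_medoids(D, medoids)
  sum(member_distances(D, part))
}

#' Cluster separation
#'
#' Scaled sum of squared inter-medoid distances over all ordered medoid
#' pairs, `2/(K(K-1)) * sum_{i != j} D^2(z_i, z_j)`; higher is better.
#'
#' @inheritParams xie_beni
#' @return Non-negative scalar (maximisation objective).
#' @export
cluster_separation <- function(D, medoids) {
  if (anyDuplicated(medoids)) stop("medoids must be distinct")
  K <- length(medoids)
  if (K < 2L) stop("need K >= 2")
  dmm <- unclass(D)[medoids, medoids, drop = FALSE]
  2 / (K * (K - 1)) * sum(dmm^2)
}

#' PBM index for a medoid clustering
#'
#' Compactness/separation composite `((1/K) * (E1/EK) * DK)^2` where `E1` is
#' the summed distance of all genes to the global medoid (the gene minimising
#' total distance, ties to the lowest index), `EK` the overall deviation of
#' the clustering and `DK` the largest inter-medoid distance. Higher is
#' better; used to seed the initial population.
#'
#' @inheritParams xie_beni
#' @return Positive scalar (maximisation objective).
#' @export
pbm_index <- function(D, medoids) {
  part <- assign_to_medoids(D, medoids)
  med <- part$medoids
  K <- length(med)
  gm <- which.min(colSums(unclass(D)))
  e1 <- sum(unclass(D)[gm, ])
  ek <- sum(member_distances(D, part))
  if (ek == 0) stop("zero overall deviation: PBM undefined")
  dk <- max(unclass(D)[med, med])
  ((1 / K) * (e1 / ek) * dk)^2
}

#' Mean silhouette width of a partition
#'
#' For each gene, `s_i = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean
#' distance to the other members of its own cluster and `b_i` the smallest
#' mean distance to another cluster; members of singleton clusters contribute
#' `s_i = 0`. The score is the mean over all genes and lies in `[-1, 1]`.
#'
#' @param D A [distance_matrix()].
#' @param P A `partition` from [assign_to_medoids()], or an integer cluster
#'   assignment vector.
#' @return Scalar in `[-1, 1]`; higher indicates tighter, better-separated
#'   clusters.
#' @export
silhouette_index <- function(D, P) {
  assignment <- if (inherits(P, "partition")) P$assignment else as.integer(P)
  n <- length(assignment)
  ks <- sort(unique(assignment))
  member <- outer(assignment, ks, "==") + 0    # n x K indicator
  sizes <- colSums(member)
  sums <- unclass(D) %*% member                # n x K distance sums
  idx <- match(assignment, ks)
  own <- cbind(seq_len(n), idx)
  a <- sums[own] / pmax(sizes[idx] - 1L, 1L)
  other <- sweep(sums, 2L, sizes, "/")
  other[own] <- Inf
  b <- apply(other, 1L, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[idx] == 1L] <- 0
  s[is.nan(s)] <- 0                            # coincident points: a = b = 0
  mean(s)
}

#' Evaluate one validity index under both distance matrices
#'
#' Each coordinate derives its own nearest-medoid partition under its own
#' matrix: coordinate 1 is the index under the expression-based distance,
#' coordinate 2 under the biology-based distance. Orientation tags record
#' whether each coordinate is minimised (`XB`, `Dev`) or maximised (`Sep`).
#'
#' @param medoids Integer vector of K distinct gene indices (valid in both
#'   matrices' shared gene universe).
#' @param index `"XB"`, `"Dev"` or `"Sep"`.
#' @param D_EB,D_BB The two [distance_matrix()] objects.
#' @param xb_variant Passed to [xie_beni()].
#' @return Numeric length-2 vector with an `orientation` attribute
#'   (`"min"`/`"max"` per coordinate); class `objective_vector`.
#' @export
evaluate_objectives <- function(medoids, index = c("XB", "Dev", "Sep"),
                                D_EB, D_BB, xb_variant = "crisp") {
  index <- match.arg(index)
  f <- switch(index,
              XB = function(D) xie_beni(D, medoids, variant = xb_variant),
              Dev = function(D) overall_deviation(D, medoids),
              Sep = function(D) cluster_separation(D, medoids))
  orient <- if (index == "Sep") c("max", "max") else c("min", "min")
  structure(c(f(D_EB), f(D_BB)), orientation = orient,
            class = "objective_vector")
}
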