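# Shared fixtures and independent oracles. The oracle implementations are
# deliberately naive (plain loops straight from the formulas) and share no
# code with the package internals.

# four elements on a line at positions 0, 1, 10, 11; D = |delta position|
line4_distance <- function() {
  pos <- c(0, 1, 10, 11)
  D <- abs(outer(pos, pos, "-"))
  dimnames(D) <- list(paste0("e", 0:3), paste0("e", 0:3))
  distance_matrix(D, source = "EB")
}

# chain ontology root <- X <- A, both edges is_a
chain_dag <- function() {
  go_dag(c("root", "X", "A"),
         data.frame(child = c("X", "A"), parent = c("root", "X"),
                    type = c("is_a", "is_a"), stringsAsFactors = FALSE))
}

# random rooted DAG: term i >= 2 attaches to a uniformly drawn earlier term
random_dag <- function(n_terms) {
  terms <- sprintf("t%02d", seq_len(n_terms))
  child <- parent <- type <- character()
  for (i in 2:n_terms) {
    child <- c(child, terms[i])
    parent <- c(parent, terms[sample.int(i - 1L, 1L)])
    type <- c(type, sample(c("is_a", "part_of"), 1L))
  }
  go_dag(terms, data.frame(child = child, parent = parent, type = type,
                           stringsAsFactors = FALSE))
}

# random Euclidean distance matrix over n points in the plane
random_distance <- function(n, source = "EB") {
  xy <- matrix(stats::runif(2L * n), n, 2L)
  D <- as.matrix(stats::dist(xy))
  dimnames(D) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  distance_matrix(D, source = source)
}

# --- brute-force validity index oracles ------------------------------------

brute_assign <- function(D, med) {
  med <- sort(med)
  vapply(seq_len(nrow(D)), function(i) {
    d <- sapply(med, function(m) D[i, m])
    which(d == min(d))[1L]          # tie -> lowest-index medoid (med sorted)
  }, integer(1L))
}

brute_xb <- function(D, med) {
  med <- sort(med)
  a <- brute_assign(D, med)
  num <- 0
  for (i in seq_len(nrow(D))) num <- num + D[med[a[i]], i]^2
  den <- Inf
  for (k in seq_along(med)) for (l in seq_along(med)) {
    if (k != l) den <- min(den, D[med[k], med[l]]^2)
  }
  num / (nrow(D) * den)
}

brute_dev <- function(D, med) {
  med <- sort(med)
  a <- brute_assign(D, med)
  s <- 0
  for (i in seq_len(nrow(D))) s <- s + D[med[a[i]], i]
  s
}

brute_sep <- function(D, med) {
  K <- length(med)
  s <- 0
  for (k in seq_len(K)) for (j in seq_len(K)) {
    if (j != k) s <- s + D[med[k], med[j]]^2
  }
  2 / (K * (K - 1)) * s
}

brute_pbm <- function(D, med) {
  med <- sort(med)
  n <- nrow(D)
  tot <- sapply(seq_len(n), function(j) sum(sapply(seq_len(n), function(i) D[j, i])))
  gm <- which(tot == min(tot))[1L]
  e1 <- tot[gm]
  ek <- brute_dev(D, med)
  dk <- 0
  for (k in seq_along(med)) for (l in seq_along(med)) dk <- max(dk, D[med[k], med[l]])
  ((1 / length(med)) * (e1 / ek) * dk)^2
}

brute_silhouette <- function(D, assignment) {
  n <- length(assignment)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assignment == assignment[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(sapply(setdiff(own, i), function(j) D[i, j]))
    b <- Inf
    for (k in setdiff(unique(assignment), assignment[i])) {
      mem <- which(assignment == k)
      b <- min(b, mean(sapply(mem, function(j) D[i, j])))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# --- dominance / hypervolume oracles ---------------------------------------

# naive O(n^2 * fronts) dominance peeling on minimised rows
peel_fronts <- function(mat) {
  idx <- seq_len(nrow(mat))
  fronts <- list()
  while (length(idx)) {
    nd <- logical(length(idx))
    for (a in seq_along(idx)) {
      dominated <- FALSE
      for (b in seq_along(idx)) {
        if (a == b) next
        u <- mat[idx[b], ]; v <- mat[idx[a], ]
        if (all(u <= v) && any(u < v)) { dominated <- TRUE; break }
      }
      nd[a] <- !dominated
    }
    fronts[[length(fronts) + 1L]] <- idx[nd]
    idx <- idx[!nd]
  }
  fronts
}

# Monte-Carlo area of the union of rectangles [p1,1] x [p2,1]
mc_hypervolume <- function(points, n_samples = 1e6) {
  u1 <- stats::runif(n_samples)
  u2 <- stats::runif(n_samples)
  covered <- rep(FALSE, n_samples)
  for (i in seq_len(nrow(points)))
    covered <- covered | (u1 >= points[i, 1L] & u2 >= points[i, 2L])
  mean(covered)
}

# tiny planted-cluster dataset used by the engine tests (fast to evolve)
small_sim <- function(seed = 5L) {
  simulate_dataset(synthetic_spec(n_genes = 30L, n_samples = 8L,
                                  k_planted = 3L, noise_sd = 0.2,
                                  terms_per_cluster = 4L, dag_depth = 2L,
                                  seed = seed))
}

small_distances <- function(sim = small_sim()) {
  suppressMessages(compute_distances(sim$X, sim$dag, sim$ann))
}

benchmark_scores <- function() {
  path <- system.file("extdata", "benchmark_silhouettes.csv",
                      package = "moclust")
  tab <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(tab[, -1L])
  rownames(m) <- tab[[1L]]
  m
}
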