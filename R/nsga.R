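#' Pareto dominance between two objective vectors
#'
#' Solution `u` dominates `v` when it is no worse on every coordinate and
#' strictly better on at least one. Maximised coordinates (per the
#' `orientation` attribute) are negated internally so every comparison is a
#' minimisation.
#'
#' @param u,v `objective_vector`s of equal length with identical orientation
#'   tags (see [evaluate_objectives()]).
#' @return `TRUE` iff `u` dominates `v`.
#' @export
dominates <- function(u, v) {
  ou <- attr(u, "orientation"); ov <- attr(v, "orientation")
  if (length(u) != length(v) || !identical(ou, ov))
    stop("objective vectors must share length and orientation tags")
  s <- ifelse(ou == "max", -1, 1)
  um <- s * as.numeric(u); vm <- s * as.numeric(v)
  all(um <= vm) && any(um < vm)
}

# dominance on minimised rows (internal hot path)
dominates_min <- function(u, v) all(u <= v) && any(u < v)

#' Fast non-dominated sorting
#'
#' Partitions a set of objective vectors into Pareto fronts: front 1 holds
#' the non-dominated vectors, front 2 those non-dominated once front 1 is
#' removed, and so on.
#'
#' @param vectors Numeric matrix, one row per solution, all coordinates
#'   minimised; or a list of `objective_vector`s (orientation handled).
#' @return List of integer vectors of row indices, one per front.
#' @export
fast_nondominated_sort <- function(vectors) {
  mat <- as_min_matrix(vectors)
  N <- nrow(mat)
  if (N == 0L) return(list())
  # dom[i, j]: does i dominate j
  dom <- matrix(FALSE, N, N)
  le <- matrix(TRUE, N, N)
  lt <- matrix(FALSE, N, N)
  for (m in seq_len(ncol(mat))) {
    o <- outer(mat[, m], mat[, m], "<=")
    le <- le & o
    lt <- lt | outer(mat[, m], mat[, m], "<")
  }
  dom <- le & lt
  counts <- colSums(dom)
  fronts <- list()
  remaining <- rep(TRUE, N)
  while (any(remaining)) {
    f <- which(remaining & counts == 0L)
    fronts[[length(fronts) + 1L]] <- f
    remaining[f] <- FALSE
    if (any(remaining))
      counts <- counts - colSums(dom[f, , drop = FALSE])
  }
  fronts
}

as_min_matrix <- function(vectors) {
  if (is.matrix(vectors)) return(vectors)
  mat <- do.call(rbind, lapply(vectors, function(v) {
    s <- ifelse(attr(v, "orientation") == "max", -1, 1)
    s * as.numeric(v)
  }))
  mat
}

#' NSGA-II crowding distance of a front
#'
#' Boundary solutions of each objective receive infinity; interior solutions
#' accumulate the normalised objective-space gap between their neighbours on
#' the front. Zero-range objectives contribute nothing.
#'
#' @param front Numeric matrix of mutually non-dominated minimised objective
#'   vectors (rows).
#' @return Numeric vector of crowding distances (may contain `Inf`).
#' @export
crowding_distance <- function(front) {
  front <- as_min_matrix(front)
  N <- nrow(front)
  if (N <= 2L) return(rep(Inf, N))
  cd <- numeric(N)
  for (m in seq_len(ncol(front))) {
    o <- order(front[, m])
    rng <- front[o[N], m] - front[o[1L], m]
    cd[o[c(1L, N)]] <- Inf
    # infinite objective values (degenerate solutions) contribute no gap
    if (is.finite(rng) && rng > 0) {
      gaps <- (front[o[3:N], m] - front[o[1:(N - 2L)], m]) / rng
      gaps[!is.finite(gaps)] <- 0
      cd[o[2:(N - 1L)]] <- cd[o[2:(N - 1L)]] + gaps
    }
  }
  cd
}

#' Binary tournament selection
#'
#' Draws two distinct members uniformly and returns the index of the one with
#' the lower Pareto rank; rank ties go to the higher crowding distance, full
#' ties are broken uniformly at random.
#'
#' @param ranks Integer Pareto ranks of the population.
#' @param crowding Crowding distances of the population.
#' @return Index of the tournament winner.
#' @export
binary_tournament <- function(ranks, crowding) {
  N <- length(ranks)
  cand <- if (N >= 2L) sample.int(N, 2L) else c(1L, 1L)
  a <- cand[1L]; b <- cand[2L]
  if (ranks[a] != ranks[b]) return(if (ranks[a] < ranks[b]) a else b)
  if (crowding[a] != crowding[b]) return(if (crowding[a] > crowding[b]) a else b)
  cand[sample.int(2L, 1L)]
}

#' (k-1)-point crossover for medoid chromosomes
#'
#' With K-1 cut points drawn from the K-1 internal boundaries of a length-K
#' chromosome, every boundary is cut and alternating single-position segments
#' are swapped between the parents. Any duplicate medoid a swap introduces is
#' repaired by replacing it with a uniformly drawn non-member, preserving the
#' distinctness invariant.
#'
#' @param p1,p2 Integer chromosomes of equal length `K >= 2`.
#' @param n Number of genes (upper bound for repair draws).
#' @return List of two child chromosomes.
#' @export
k1_point_crossover <- function(p1, p2, n) {
  K <- length(p1)
  stopifnot(length(p2) == K, K >= 2L)
  swap <- seq(2L, K, by = 2L)
  c1 <- p1; c2 <- p2
  c1[swap] <- p2[swap]
  c2[swap] <- p1[swap]
  list(repair_chromosome(c1, n), repair_chromosome(c2, n))
}

repair_chromosome <- function(ch, n) {
  while (anyDuplicated(ch)) {
    i <- which(duplicated(ch))[1L]
    pool <- setdiff(seq_len(n), ch)
    ch[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
  }
  ch
}

#' Controller-random mutation
#'
#' Replaces one uniformly chosen chromosome position with a uniformly chosen
#' gene index not already in the chromosome.
#'
#' @param ch Integer chromosome.
#' @param n Number of genes; must exceed `length(ch)`.
#' @return Mutated chromosome (distinct entries).
#' @export
controller_random_mutation <- function(ch, n) {
  stopifnot(length(ch) < n)
  pos <- sample.int(length(ch), 1L)
  pool <- setdiff(seq_len(n), ch)
  ch[pos] <- if (length(pool) == 1L) pool else sample(pool, 1L)
  ch
}

random_chromosome <- function(n, K) sort(sample.int(n, K))

#' Run configuration for the evolutionary engine
#'
#' Defaults follow the experimental setup the method was designed with:
#' 100 generations, population 50, crossover probability 0.80, mutation
#' probability 0.01 (applied per individual), 10 stall generations, Xie-Beni
#' objective, both local-search strategies.
#'
#' @param K Number of clusters (chromosome length), `>= 2`.
#' @param pop_size Even population size `N`.
#' @param generations Maximum number of generations.
#' @param crossover_prob,mutation_prob Operator probabilities in `[0, 1]`.
#' @param stall_generations Stop after this many generations without change
#'   in the front's objective vectors.
#' @param index Validity index used as the paired objective:
#'   `"XB"`, `"Dev"` or `"Sep"`.
#' @param local_search `"none"`, `"pr"`, `"pls"` or `"both"`.
#' @param seed Integer seed fixing all randomness of the run.
#' @param xb_variant `"crisp"` (default) or `"allpairs"` Xie-Beni reading.
#' @param sga_pop,sga_generations Budget of the single-objective GA that
#'   seeds half the initial population by maximising PBM.
#' @param pls_max_explored Cap on solutions explored per Pareto-local-search
#'   call (full one-swap neighbourhoods are always enumerated).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(K, pop_size = 50L, generations = 100L,
                       crossover_prob = 0.8, mutation_prob = 0.01,
                       stall_generations = 10L,
                       index = c("XB", "Dev", "Sep"),
                       local_search = c("both", "none", "pr", "pls"),
                       seed = 1L, xb_variant = "crisp",
                       sga_pop = 50L, sga_generations = 50L,
                       pls_max_explored = 500L) {
  index <- match.arg(index)
  local_search <- match.arg(local_search)
  stopifnot(K >= 2L, pop_size %% 2L == 0L, generations >= 0L,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1)
  structure(list(K = as.integer(K), pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 stall_generations = as.integer(stall_generations),
                 index = index, local_search = local_search,
                 seed = as.integer(seed), xb_variant = xb_variant,
                 sga_pop = as.integer(sga_pop),
                 sga_generations = as.integer(sga_generations),
                 pls_max_explored = as.integer(pls_max_explored)),
            class = "run_config")
}

# Cached evaluator over both distance matrices. Returns minimised length-2
# vectors; raw values are recovered with the stored sign. Chromosomes are
# evaluated as sets (sorted), so the cache key is order-independent.
make_evaluator <- function(D_EB, D_BB, index, xb_variant = "crisp") {
  eb <- unclass(D_EB); bb <- unclass(D_BB)
  n <- nrow(eb)
  sign <- if (index == "Sep") -1 else 1
  one <- function(D, med) {
    dm <- D[, med, drop = FALSE]
    switch(index,
           XB = {
             dmm <- D[med, med, drop = FALSE]
             sep2 <- min(dmm[upper.tri(dmm)]^2)
             num <- if (xb_variant == "crisp") {
               d <- dm[, 1L]
               for (k in seq_along(med)[-1L]) d <- pmin(d, dm[, k])
               sum(d * d)
             } else sum(dm * dm)
             if (sep2 > 0) num / (n * sep2) else Inf
           },
           Dev = {
             d <- dm[, 1L]
             for (k in seq_along(med)[-1L]) d <- pmin(d, dm[, k])
             sum(d)
           },
           Sep = {
             K <- length(med)
             dmm <- D[med, med, drop = FALSE]
             -(2 / (K * (K - 1)) * sum(dmm * dmm))  # negated: maximisation
           })
  }
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  ev <- function(ch) {
    med <- sort.int(ch)
    key <- paste(med, collapse = " ")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- c(one(eb, med), one(bb, med))
    cache[[key]] <- val
    val
  }
  # batch evaluation of the one-swap neighbourhood base + {g}, g in pool:
  # returns a |pool| x 2 matrix of minimised objective vectors
  neigh_one <- function(D, base, pool) {
    Dpool <- D[, pool, drop = FALSE]
    switch(index,
           XB = {
             dbase <- D[, base[1L]]
             for (k in seq_along(base)[-1L]) dbase <- pmin(dbase, D[, base[k]])
             dbb <- D[base, base, drop = FALSE]
             m0 <- if (length(base) > 1L) min(dbb[upper.tri(dbb)]) else Inf
             dbp <- D[base, pool, drop = FALSE]
             mg <- dbp[1L, ]
             for (k in seq_along(base)[-1L]) mg <- pmin(mg, dbp[k, ])
             sep2 <- pmin(m0, mg)^2
             num <- if (xb_variant == "crisp") {
               dmin <- pmin(Dpool, dbase)
               colSums(dmin * dmin)
             } else {
               sum(D[, base]^2) + colSums(Dpool * Dpool)
             }
             ifelse(sep2 > 0, num / (n * sep2), Inf)
           },
           Dev = {
             dbase <- D[, base[1L]]
             for (k in seq_along(base)[-1L]) dbase <- pmin(dbase, D[, base[k]])
             colSums(pmin(Dpool, dbase))
           },
           Sep = {
             K <- length(base) + 1L
             s0 <- sum(D[base, base]^2)
             sg <- 2 * colSums(D[base, pool, drop = FALSE]^2)
             -(2 / (K * (K - 1)) * (s0 + sg))
           })
  }
  neigh <- function(base, pool) {
    cbind(neigh_one(eb, base, pool), neigh_one(bb, base, pool))
  }
  attr(ev, "sign") <- sign
  attr(ev, "orientation") <- if (index == "Sep") c("max", "max") else c("min", "min")
  attr(ev, "n") <- n
  attr(ev, "neigh") <- neigh
  ev
}

eval_population <- function(evaluator, chroms) {
  do.call(rbind, lapply(chroms, evaluator))
}

# PBM-maximising single genetic algorithm used to seed half the initial
# population; elitist (mu + lambda) truncation on the PBM score.
sga_pbm <- function(D_EB, K, n, pop_size, generations,
                    crossover_prob, mutation_prob) {
  D <- unclass(D_EB)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  pbm <- function(ch) {
    key <- paste(sort.int(ch), collapse = " ")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- pbm_index(D_EB, ch)
    cache[[key]] <- val
    val
  }
  pop <- replicate(pop_size, random_chromosome(n, K), simplify = FALSE)
  fit <- vapply(pop, pbm, numeric(1L))
  for (g in seq_len(generations)) {
    off <- vector("list", pop_size)
    i <- 1L
    while (i <= pop_size) {
      pick <- function() {
        cand <- sample.int(pop_size, 2L)
        if (fit[cand[1L]] >= fit[cand[2L]]) cand[1L] else cand[2L]
      }
      p1 <- pop[[pick()]]; p2 <- pop[[pick()]]
      kids <- if (stats::runif(1L) < crossover_prob)
        k1_point_crossover(p1, p2, n) else list(p1, p2)
      for (kid in kids) {
        if (i > pop_size) break
        if (stats::runif(1L) < mutation_prob)
          kid <- controller_random_mutation(kid, n)
        off[[i]] <- kid
        i <- i + 1L
      }
    }
    offfit <- vapply(off, pbm, numeric(1L))
    all_pop <- c(pop, off)
    all_fit <- c(fit, offfit)
    keep <- order(all_fit, decreasing = TRUE)[seq_len(pop_size)]
    pop <- all_pop[keep]
    fit <- all_fit[keep]
  }
  pop[order(fit, decreasing = TRUE)]
}

#' Build the initial population
#'
#' Half the chromosomes are drawn uniformly at random; the other half are the
#' best individuals of a single-objective genetic algorithm maximising the
#' PBM index under the expression-based distance, which seeds the
#' multi-objective search with good compact solutions.
#'
#' @param N Even population size.
#' @param D_EB Expression-based [distance_matrix()].
#' @param K Number of clusters.
#' @param config A [run_config()] supplying operator rates and SGA budget.
#' @return List of `N` chromosomes.
#' @export
init_population <- function(N, D_EB, K, config) {
  stopifnot(N %% 2L == 0L)
  n <- nrow(D_EB)
  half <- N %/% 2L
  rand <- replicate(half, random_chromosome(n, K), simplify = FALSE)
  sga <- sga_pbm(D_EB, K, n, config$sga_pop, config$sga_generations,
                 config$crossover_prob, config$mutation_prob)
  c(rand, sga[seq_len(half)])
}

front_key <- function(obj_mat) {
  paste(sort(apply(round(obj_mat / 1e-9) * 1e-9, 1L,
                   paste, collapse = ",")), collapse = ";")
}

chrom_key <- function(ch) paste(sort.int(ch), collapse = " ")

# deduplicate chromosomes by medoid-set identity, keeping first occurrence
dedupe_solutions <- function(chroms, objs) {
  keys <- vapply(chroms, chrom_key, character(1L))
  keep <- !duplicated(keys)
  list(chroms = chroms[keep], objs = objs[keep, , drop = FALSE])
}

#' Evolve a Pareto front of medoid clusterings
#'
#' NSGA-II generation loop with medoid-encoded chromosomes and a paired
#' objective (one validity index evaluated under the expression-based and the
#' biology-based distance). Each generation builds an offspring population by
#' binary tournament, (k-1)-point crossover and controller-random mutation,
#' merges it with the parents, keeps the first non-dominated front, applies
#' multi-objective path-relinking and/or Pareto local search to it, and forms
#' the next population from the resulting front (padded with random
#' chromosomes or truncated by crowding distance to size `N`). The run stops
#' at the generation budget or after `stall_generations` generations without
#' change in the front's objective vectors.
#'
#' @param config A [run_config()].
#' @param D_EB,D_BB [distance_matrix()] objects over the same gene universe.
#' @return An object of class `pareto_front`: list with `chromosomes` (sorted
#'   medoid vectors), `objectives` (raw values, one row per solution),
#'   `orientation`, `index`, `gene_ids`, `config`, `generations_run` and
#'   `stop_reason`. All solutions are mutually non-dominated.
#' @export
evolve <- function(config, D_EB, D_BB) {
  stopifnot(inherits(config, "run_config"))
  if (!identical(rownames(D_EB), rownames(D_BB)))
    stop("distance matrices must share an identical gene universe")
  n <- nrow(D_EB)
  K <- config$K
  if (K >= n) stop("need K < n")
  N <- config$pop_size
  set.seed(config$seed)
  evaluator <- make_evaluator(D_EB, D_BB, config$index, config$xb_variant)

  P <- init_population(N, D_EB, K, config)
  P_obj <- eval_population(evaluator, P)

  current_front <- function(chroms, objs) {
    dd <- dedupe_solutions(chroms, objs)
    f1 <- fast_nondominated_sort(dd$objs)[[1L]]
    list(chroms = dd$chroms[f1], objs = dd$objs[f1, , drop = FALSE])
  }

  fr <- current_front(P, P_obj)
  gens_run <- 0L
  stop_reason <- "generation budget reached"
  stall <- 0L
  last_key <- front_key(fr$objs)

  if (config$generations > 0L) {
    for (v in seq_len(config$generations)) {
      ranks_cd <- population_ranks(P_obj)
      Q <- make_offspring(P, ranks_cd$rank, ranks_cd$crowding, config, n)
      Q_obj <- eval_population(evaluator, Q)
      R <- c(P, Q)
      R_obj <- rbind(P_obj, Q_obj)
      fr <- current_front(R, R_obj)
      if (config$local_search %in% c("pr", "both"))
        fr <- mopr(fr$chroms, fr$objs, evaluator)
      if (config$local_search %in% c("pls", "both"))
        fr <- pls(fr$chroms, fr$objs, evaluator,
                  max_explored = config$pls_max_explored)
      gens_run <- v
      key <- front_key(fr$objs)
      if (identical(key, last_key)) stall <- stall + 1L else stall <- 0L
      last_key <- key
      # next population: the front, padded with random solutions or truncated
      # by descending crowding distance
      P <- fr$chroms
      P_obj <- fr$objs
      if (length(P) > N) {
        cd <- crowding_distance(P_obj)
        keep <- order(cd, decreasing = TRUE)[seq_len(N)]
        P <- P[keep]
        P_obj <- P_obj[keep, , drop = FALSE]
      } else if (length(P) < N) {
        pad <- replicate(N - length(P), random_chromosome(n, K),
                         simplify = FALSE)
        P <- c(P, pad)
        P_obj <- rbind(P_obj, eval_population(evaluator, pad))
      }
      if (stall >= config$stall_generations) {
        stop_reason <- "objective vectors stalled"
        break
      }
    }
  } else {
    stop_reason <- "zero generations requested"
  }

  sgn <- attr(evaluator, "sign")
  structure(list(chromosomes = lapply(fr$chroms, sort.int),
                 objectives = fr$objs * sgn,
                 orientation = attr(evaluator, "orientation"),
                 index = config$index,
                 gene_ids = rownames(D_EB),
                 config = config,
                 generations_run = gens_run,
                 stop_reason = stop_reason),
            class = "pareto_front")
}

population_ranks <- function(obj_mat) {
  fronts <- fast_nondominated_sort(obj_mat)
  rank <- integer(nrow(obj_mat))
  cd <- numeric(nrow(obj_mat))
  for (i in seq_along(fronts)) {
    rank[fronts[[i]]] <- i
    cd[fronts[[i]]] <- crowding_distance(obj_mat[fronts[[i]], , drop = FALSE])
  }
  list(rank = rank, crowding = cd)
}

make_offspring <- function(P, rank, crowding, config, n) {
  N <- config$pop_size
  Q <- vector("list", N)
  i <- 1L
  while (i <= N) {
    p1 <- P[[binary_tournament(rank, crowding)]]
    p2 <- P[[binary_tournament(rank, crowding)]]
    kids <- if (stats::runif(1L) < config$crossover_prob)
      k1_point_crossover(p1, p2, n) else list(p1, p2)
    for (kid in kids) {
      if (i > N) break
      if (stats::runif(1L) < config$mutation_prob)
        kid <- controller_random_mutation(kid, n)
      Q[[i]] <- kid
      i <- i + 1L
    }
  }
  Q
}

#' @export
print.pareto_front <- function(x, ...) {
  cat("Pareto front:", length(x$chromosomes), "non-dominated solution(s)\n")
  cat("index:", x$index, " K:", x$config$K,
      " generations run:", x$generations_run,
      " (", x$stop_reason, ")\n", sep = "")
  invisible(x)
}
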