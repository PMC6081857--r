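#' One-swap path-relinking candidates
#'
#' All chromosomes obtained by removing a single medoid present in `current`
#' but not in `guiding` and inserting a single medoid present in `guiding`
#' but not in `current`; there are `d^2` of them when the medoid sets differ
#' in `d` elements.
#'
#' @param current,guiding Integer chromosomes over the same gene universe.
#' @return List of candidate chromosomes (sorted); empty when the medoid
#'   sets coincide.
#' @export
pr_step_candidates <- function(current, guiding) {
  out_set <- setdiff(current, guiding)
  in_set <- setdiff(guiding, current)
  cands <- list()
  for (r in out_set) {
    base <- current[current != r]
    for (a in in_set) {
      cands[[length(cands) + 1L]] <- sort.int(c(base, a))
    }
  }
  cands
}

# deterministic total order on chromosomes (lexicographic on sorted medoids)
chrom_lex_order <- function(chroms) {
  keys <- vapply(chroms, function(ch)
    paste(sprintf("%09d", sort.int(ch)), collapse = " "), character(1L))
  order(keys)
}

# pick the best-move candidate: Pareto rank, then crowding distance, then
# lowest first (minimised) objective, then lexicographic chromosome order
best_move <- function(chroms, objs) {
  fronts <- fast_nondominated_sort(objs)
  f1 <- fronts[[1L]]
  cd <- crowding_distance(objs[f1, , drop = FALSE])
  lex <- integer(length(f1))
  lex[chrom_lex_order(chroms[f1])] <- seq_along(f1)
  ord <- order(-cd, objs[f1, 1L], lex)
  f1[ord[1L]]
}

#' Path-relinking between two elite solutions
#'
#' Walks the medoid-swap trajectory from `start` to `guiding`: at each step
#' every candidate produced by [pr_step_candidates()] is evaluated, the
#' candidates are non-dominated- and crowding-sorted, and the top-ranked one
#' becomes the new start. The walk takes exactly `d` steps when the sets
#' differ in `d` medoids and ends at the guiding medoid set.
#'
#' @param start,guiding Integer chromosomes.
#' @param evaluator Cached evaluator from the engine (minimised objectives).
#' @return List of chromosomes: start, each chosen intermediate, and guiding.
#' @export
path_relinking <- function(start, guiding, evaluator) {
  path <- list(sort.int(start))
  cur <- start
  while (length(setdiff(cur, guiding)) > 0L) {
    cands <- pr_step_candidates(cur, guiding)
    objs <- eval_population(evaluator, cands)
    cur <- cands[[best_move(cands, objs)]]
    path[[length(path) + 1L]] <- cur
  }
  # `start` and `guiding` are both included; when they coincide the path is
  # the single start solution
  path
}

#' Multi-objective path-relinking over a front
#'
#' Orders the front by crowding distance (all members share rank 1), pairs
#' the two most prominent solutions, then chains: the previous guiding
#' solution becomes the next start and the next not-yet-considered front
#' member (by medoid-set identity) the next guiding, until every solution has
#' been selected. Path-relinking runs in both directions for each pair; the
#' harvested intermediate pool is merged with the input front, re-sorted, and
#' the first non-dominated front returned.
#'
#' @param chroms List of front chromosomes.
#' @param objs Matrix of their minimised objective vectors.
#' @param evaluator Cached evaluator.
#' @return List with `chroms` and `objs` of the resulting front.
#' @export
mopr <- function(chroms, objs, evaluator) {
  m <- length(chroms)
  if (m < 2L) return(list(chroms = chroms, objs = objs))
  cd <- crowding_distance(objs)
  lex <- integer(m)
  lex[chrom_lex_order(chroms)] <- seq_len(m)
  ord <- order(-cd, objs[, 1L], lex)
  pool <- list()
  for (i in seq_len(m - 1L)) {
    c1 <- chroms[[ord[i]]]
    c2 <- chroms[[ord[i + 1L]]]
    pool <- c(pool, path_relinking(c1, c2, evaluator),
              path_relinking(c2, c1, evaluator))
  }
  all_ch <- c(chroms, pool)
  all_obj <- rbind(objs, eval_population(evaluator, pool))
  dd <- dedupe_solutions(all_ch, all_obj)
  f1 <- fast_nondominated_sort(dd$objs)[[1L]]
  list(chroms = dd$chroms[f1], objs = dd$objs[f1, , drop = FALSE])
}

#' Pareto local search over a front
#'
#' Implements the selection / neighbourhood-exploration / acceptance loop:
#' an unexplored solution `C` is drawn at random, one of its medoids is
#' chosen at random, and the full one-swap neighbourhood replacing that
#' medoid with every gene not in `C` is evaluated. Each neighbour not
#' dominated by `C` enters the archive unexplored, and the archive is pruned
#' of solutions the neighbour dominates. `C` is then marked explored, and the
#' loop continues until no unexplored solutions remain (or the exploration
#' cap is reached). The first non-dominated front of the archive is returned.
#'
#' @param chroms List of front chromosomes.
#' @param objs Matrix of their minimised objective vectors.
#' @param evaluator Cached evaluator.
#' @param max_explored Exploration cap for large instances.
#' @return List with `chroms` and `objs` of the resulting front.
#' @export
pls <- function(chroms, objs, evaluator, max_explored = 500L) {
  n <- attr(evaluator, "n")
  neigh <- attr(evaluator, "neigh")
  arc_ch <- lapply(chroms, sort.int)
  arc_key <- vapply(arc_ch, chrom_key, character(1L))
  keep0 <- !duplicated(arc_key)
  arc_ch <- arc_ch[keep0]
  arc_key <- arc_key[keep0]
  arc_obj <- objs[keep0, , drop = FALSE]
  arc_exp <- rep(FALSE, length(arc_ch))
  explored_count <- 0L
  repeat {
    a0 <- which(!arc_exp)
    if (length(a0) == 0L || explored_count >= max_explored) break
    ci <- if (length(a0) == 1L) a0 else sample(a0, 1L)
    C_ch <- arc_ch[[ci]]
    C_obj <- arc_obj[ci, ]
    C_key <- arc_key[ci]
    pos <- sample.int(length(C_ch), 1L)
    pool <- setdiff(seq_len(n), C_ch)
    base <- C_ch[-pos]
    nb_obj <- neigh(base, pool)
    # acceptance: neighbours C' with !(C dominates C')
    acc <- which(!(C_obj[1L] <= nb_obj[, 1L] & C_obj[2L] <= nb_obj[, 2L] &
                     (C_obj[1L] < nb_obj[, 1L] | C_obj[2L] < nb_obj[, 2L])))
    for (i in acc) {
      o <- nb_obj[i, ]
      nb <- sort.int(c(base, pool[i]))
      key <- chrom_key(nb)
      at <- match(key, arc_key)
      if (is.na(at)) {
        arc_ch[[length(arc_ch) + 1L]] <- nb
        arc_key <- c(arc_key, key)
        arc_obj <- rbind(arc_obj, o)
        arc_exp <- c(arc_exp, FALSE)
        at <- length(arc_ch)
      }
      # prune archive members the accepted neighbour dominates
      domd <- which(o[1L] <= arc_obj[, 1L] & o[2L] <= arc_obj[, 2L] &
                      (o[1L] < arc_obj[, 1L] | o[2L] < arc_obj[, 2L]))
      domd <- setdiff(domd, at)
      if (length(domd)) {
        arc_ch <- arc_ch[-domd]
        arc_key <- arc_key[-domd]
        arc_obj <- arc_obj[-domd, , drop = FALSE]
        arc_exp <- arc_exp[-domd]
      }
    }
    at_c <- match(C_key, arc_key)
    if (!is.na(at_c)) arc_exp[at_c] <- TRUE
    explored_count <- explored_count + 1L
  }
  f1 <- fast_nondominated_sort(arc_obj)[[1L]]
  list(chroms = arc_ch[f1], objs = arc_obj[f1, , drop = FALSE])
}
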