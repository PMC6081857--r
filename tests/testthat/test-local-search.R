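# a tiny evaluator over an explicit solution universe is enough to exercise
# the local-search contracts
toy_evaluator <- function(n = 6L) {
  set.seed(99)
  D_EB <- random_distance(n, "EB")
  D_BB <- random_distance(n, "BB")
  rownames(D_BB) <- colnames(D_BB) <- rownames(D_EB)
  moclust:::make_evaluator(D_EB, D_BB, "XB", "crisp")
}

test_that("path-relinking step candidates enumerate remove/insert pairs", {
  cands <- pr_step_candidates(c(1L, 2L, 3L), c(1L, 4L, 5L))
  expect_length(cands, 4L)
  keys <- sort(vapply(cands, paste, character(1L), collapse = " "))
  expect_equal(keys, sort(c("1 3 4", "1 3 5", "1 2 4", "1 2 5")))
  one <- pr_step_candidates(c(1L, 2L, 3L), c(1L, 2L, 6L))
  expect_length(one, 1L)
  expect_equal(one[[1L]], c(1L, 2L, 6L))
  expect_length(pr_step_candidates(c(1L, 2L), c(2L, 1L)), 0L)
})

test_that("path-relinking trajectories take d one-swap steps to the guide", {
  ev <- toy_evaluator(8L)
  set.seed(12)
  for (rep in 1:10) {
    start <- sort(sample.int(8L, 3L))
    guiding <- sort(sample.int(8L, 3L))
    path <- path_relinking(start, guiding, ev)
    d <- length(setdiff(start, guiding))
    expect_length(path, d + 1L)
    expect_setequal(path[[length(path)]], guiding)
    if (length(path) > 1L) {
      for (i in 2:length(path)) {
        expect_equal(length(setdiff(path[[i - 1L]], path[[i]])), 1L)
      }
    }
  }
  expect_equal(path_relinking(c(1L, 2L), c(2L, 1L), ev), list(c(1L, 2L)))
})

test_that("chosen best moves match exhaustive trajectory enumeration", {
  ev <- toy_evaluator(7L)
  # independent re-implementation of the selection rule with naive loops
  naive_pick <- function(cands) {
    objs <- t(vapply(cands, ev, numeric(2L)))
    ndom <- vapply(seq_along(cands), function(a) {
      !any(vapply(seq_along(cands), function(b) {
        b != a && all(objs[b, ] <= objs[a, ]) && any(objs[b, ] < objs[a, ])
      }, logical(1L)))
    }, logical(1L))
    f1 <- which(ndom)
    cd <- crowding_distance(objs[f1, , drop = FALSE])
    lexkey <- vapply(cands[f1], function(ch)
      paste(sprintf("%09d", ch), collapse = " "), character(1L))
    f1[order(-cd, objs[f1, 1L], lexkey)][1L]
  }
  set.seed(21)
  for (rep in 1:10) {
    start <- sort(sample.int(7L, 3L))
    guiding <- sort(sample.int(7L, 3L))
    if (setequal(start, guiding)) next
    path <- path_relinking(start, guiding, ev)
    cur <- start
    for (i in 2:length(path)) {
      cands <- pr_step_candidates(cur, guiding)
      expect_equal(path[[i]], cands[[naive_pick(cands)]])
      cur <- path[[i]]
    }
  }
})

make_front <- function(ev, n, K, n_try = 30L) {
  sols <- unique(lapply(seq_len(n_try), function(i) sort(sample.int(n, K))))
  objs <- t(vapply(sols, ev, numeric(2L)))
  f1 <- fast_nondominated_sort(objs)[[1L]]
  list(chroms = sols[f1], objs = objs[f1, , drop = FALSE])
}

test_that("MOPR returns a mutually non-dominated, no-worse front", {
  ev <- toy_evaluator(8L)
  set.seed(31)
  fr <- make_front(ev, 8L, 3L)
  out <- mopr(fr$chroms, fr$objs, ev)
  # mutual non-dominance
  m <- nrow(out$objs)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j)
      expect_false(all(out$objs[i, ] <= out$objs[j, ]) &&
                     any(out$objs[i, ] < out$objs[j, ]))
  }
  # no output solution dominated by any input solution
  for (i in seq_len(m)) for (j in seq_len(nrow(fr$objs))) {
    expect_false(all(fr$objs[j, ] <= out$objs[i, ]) &&
                   any(fr$objs[j, ] < out$objs[i, ]))
  }
  # hypervolume can only improve under a shared normalisation
  hv <- hypervolume_compare(list(fr$objs, out$objs))
  expect_gte(hv[2L] + 1e-12, hv[1L])
  # singleton front unchanged
  single <- mopr(fr$chroms[1L], fr$objs[1L, , drop = FALSE], ev)
  expect_equal(single$chroms, lapply(fr$chroms[1L], sort.int))
})

test_that("PLS leaves an exhaustively verified local optimum unchanged", {
  ev <- toy_evaluator(5L)
  all_sols <- combn(5L, 2L, simplify = FALSE)
  objs <- t(vapply(all_sols, ev, numeric(2L)))
  f1 <- fast_nondominated_sort(objs)[[1L]]
  front <- list(chroms = all_sols[f1], objs = objs[f1, , drop = FALSE])
  set.seed(41)
  out <- pls(front$chroms, front$objs, ev)
  key <- function(chs) sort(vapply(chs, paste, character(1L), collapse = " "))
  expect_equal(key(out$chroms), key(front$chroms))
})

test_that("PLS output is non-dominated and no worse than its input", {
  ev <- toy_evaluator(9L)
  set.seed(51)
  for (rep in 1:5) {
    fr <- make_front(ev, 9L, 3L)
    out <- pls(fr$chroms, fr$objs, ev)
    m <- nrow(out$objs)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j)
          expect_false(all(out$objs[i, ] <= out$objs[j, ]) &&
                         any(out$objs[i, ] < out$objs[j, ]))
      }
      for (j in seq_len(nrow(fr$objs))) {
        expect_false(all(fr$objs[j, ] <= out$objs[i, ]) &&
                       any(fr$objs[j, ] < out$objs[i, ]))
      }
    }
  }
})
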