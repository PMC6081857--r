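ov <- function(x, orientation = c("min", "min")) {
  structure(x, orientation = orientation, class = "objective_vector")
}

test_that("dominance follows the standard definition with orientations", {
  expect_true(dominates(ov(c(0.2, 0.3)), ov(c(0.4, 0.3))))
  expect_false(dominates(ov(c(0.4, 0.3)), ov(c(0.2, 0.3))))
  expect_false(dominates(ov(c(1, 1)), ov(c(1, 1))))
  expect_false(dominates(ov(c(0.1, 0.5)), ov(c(0.5, 0.1))))
  expect_false(dominates(ov(c(0.5, 0.1)), ov(c(0.1, 0.5))))
  # maximisation flips the comparison
  expect_true(dominates(ov(c(3, 3), c("max", "max")),
                        ov(c(2, 3), c("max", "max"))))
  expect_error(dominates(ov(c(1, 2)), ov(c(1, 2), c("max", "min"))),
               "orientation")
})

test_that("fast non-dominated sort matches simple cases and the peeling oracle", {
  expect_equal(fast_nondominated_sort(rbind(c(1, 1), c(2, 2))),
               list(1L, 2L))
  expect_equal(fast_nondominated_sort(rbind(c(1, 2), c(2, 1))),
               list(c(1L, 2L)))
  set.seed(11)
  for (rep in 1:20) {
    mat <- matrix(runif(2 * sample(3:12, 1L)), ncol = 2L)
    got <- fast_nondominated_sort(mat)
    want <- peel_fronts(mat)
    expect_equal(lapply(got, sort), lapply(want, sort))
  }
})

test_that("crowding distance gives boundaries infinity and interiors gap sums", {
  cd <- crowding_distance(rbind(c(0, 1), c(0.5, 0.5), c(1, 0)))
  expect_equal(cd, c(Inf, 2, Inf))
  expect_equal(crowding_distance(rbind(c(0.3, 0.3))), Inf)
  # interior duplicates contribute zero-width gaps
  cd2 <- crowding_distance(rbind(c(0, 1), c(0.5, 0.5), c(0.5, 0.5), c(1, 0)))
  expect_equal(cd2[2L], cd2[3L])
  expect_lt(cd2[2L], 2)
})

test_that("binary tournament prefers rank, then crowding, then rng", {
  set.seed(1)
  ranks <- c(1L, 2L)
  crowd <- c(0, 0)
  wins <- replicate(20, binary_tournament(ranks, crowd))
  expect_true(all(wins == 1L))
  wins2 <- replicate(20, binary_tournament(c(1L, 1L), c(3, Inf)))
  expect_true(all(wins2 == 2L))
  set.seed(2)
  a <- replicate(50, binary_tournament(c(1L, 1L), c(1, 1)))
  set.seed(2)
  b <- replicate(50, binary_tournament(c(1L, 1L), c(1, 1)))
  expect_identical(a, b)        # deterministic under a seed
  expect_setequal(unique(a), c(1L, 2L))
})

test_that("(k-1)-point crossover swaps alternating positions and repairs", {
  set.seed(3)
  kids <- k1_point_crossover(c(1L, 6L, 19L, 83L), c(2L, 7L, 20L, 90L), 100L)
  expect_equal(kids[[1L]], c(1L, 7L, 19L, 90L))
  expect_equal(kids[[2L]], c(2L, 6L, 20L, 83L))
  same <- k1_point_crossover(c(3L, 8L, 12L), c(3L, 8L, 12L), 20L)
  expect_equal(same[[1L]], c(3L, 8L, 12L))
  # overlapping parents force repair; distinctness must always hold
  for (rep in 1:50) {
    p1 <- sample.int(10L, 4L)
    p2 <- sample.int(10L, 4L)
    kk <- k1_point_crossover(p1, p2, 10L)
    expect_false(anyDuplicated(kk[[1L]]) > 0)
    expect_false(anyDuplicated(kk[[2L]]) > 0)
  }
})

test_that("controller-random mutation changes one position to a non-member", {
  set.seed(4)
  for (rep in 1:30) {
    ch <- sample.int(50L, 4L)
    mut <- controller_random_mutation(ch, 50L)
    expect_equal(sum(mut != ch), 1L)
    expect_false(mut[mut != ch] %in% ch)
    expect_false(anyDuplicated(mut) > 0)
  }
  # only one non-member available: it must be the replacement
  mut <- controller_random_mutation(c(1L, 2L, 3L), 4L)
  expect_true(4L %in% mut)
})

test_that("initial population is half random, half PBM-seeded, all valid", {
  d <- small_distances()
  set.seed(5)
  cfg <- run_config(K = 3L, pop_size = 20L, sga_pop = 20L,
                    sga_generations = 10L)
  pop <- init_population(20L, d$D_EB, 3L, cfg)
  expect_length(pop, 20L)
  n <- nrow(d$D_EB)
  for (ch in pop) {
    expect_length(ch, 3L)
    expect_false(anyDuplicated(ch) > 0)
    expect_true(all(ch >= 1L & ch <= n))
  }
  # the SGA half should carry better PBM values than the random half
  reps <- replicate(5, {
    p <- init_population(20L, d$D_EB, 3L, cfg)
    pbm_rand <- mean(vapply(p[1:10], function(ch) pbm_index(d$D_EB, ch),
                            numeric(1L)))
    pbm_sga <- mean(vapply(p[11:20], function(ch) pbm_index(d$D_EB, ch),
                           numeric(1L)))
    pbm_sga >= pbm_rand
  })
  expect_true(all(reps))
})

test_that("evolve honours the degenerate and deterministic contracts", {
  d <- small_distances()
  cfg0 <- run_config(K = 3L, pop_size = 10L, generations = 0L, seed = 8L,
                     sga_pop = 10L, sga_generations = 3L)
  fr0 <- evolve(cfg0, d$D_EB, d$D_BB)
  expect_s3_class(fr0, "pareto_front")
  expect_identical(fr0$stop_reason, "zero generations requested")
  cfg <- run_config(K = 3L, pop_size = 10L, generations = 4L, seed = 8L,
                    sga_pop = 10L, sga_generations = 3L)
  fr1 <- evolve(cfg, d$D_EB, d$D_BB)
  fr2 <- evolve(cfg, d$D_EB, d$D_BB)
  expect_identical(fr1$chromosomes, fr2$chromosomes)
  expect_identical(fr1$objectives, fr2$objectives)
  # output must be mutually non-dominated (exhaustive check, raw scale)
  for (fr in list(fr0, fr1)) {
    m <- length(fr$chromosomes)
    if (m > 1L) {
      s <- ifelse(fr$orientation == "max", -1, 1)
      mm <- sweep(fr$objectives, 2L, s, "*")
      for (i in 1:m) for (j in 1:m) {
        if (i != j)
          expect_false(all(mm[i, ] <= mm[j, ]) && any(mm[i, ] < mm[j, ]))
      }
    }
  }
})

test_that("the engine evaluator agrees with the exported index functions", {
  d <- small_distances()
  ev <- moclust:::make_evaluator(d$D_EB, d$D_BB, "XB", "crisp")
  set.seed(10)
  for (rep in 1:20) {
    med <- sample.int(nrow(d$D_EB), 3L)
    # the exported index refuses coincident medoids (distance 0 under the
    # biology matrix); the engine treats them as infinitely bad instead
    bb_sep <- unclass(d$D_BB)[med, med][upper.tri(diag(3L))]
    if (any(bb_sep == 0)) {
      expect_equal(ev(med)[2L], Inf)
    } else {
      expect_equal(ev(med),
                   c(xie_beni(d$D_EB, med), xie_beni(d$D_BB, med)),
                   tolerance = 1e-12)
    }
  }
  evs <- moclust:::make_evaluator(d$D_EB, d$D_BB, "Sep", "crisp")
  med <- c(2L, 9L, 17L)
  expect_equal(evs(med),
               -c(cluster_separation(d$D_EB, med),
                  cluster_separation(d$D_BB, med)),
               tolerance = 1e-12)
  # batch neighbourhood evaluation agrees with scalar evaluation
  nb <- attr(ev, "neigh")
  base <- c(4L, 12L)
  pool <- setdiff(seq_len(nrow(d$D_EB)), c(base, 20L))[1:10]
  got <- nb(base, pool)
  want <- t(vapply(pool, function(g) ev(c(base, g)), numeric(2L)))
  expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)
})
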