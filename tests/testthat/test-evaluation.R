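test_that("front normalisation maps to the unit square and preserves order", {
  expect_equal(normalize_front(rbind(c(3, 4))), rbind(c(0, 0)))
  got <- normalize_front(rbind(c(2, 8), c(4, 4)))
  expect_equal(got, rbind(c(0, 1), c(1, 0)))
  # dominance preserved under the affine map
  set.seed(13)
  pts <- matrix(runif(20), ncol = 2L)
  norm <- normalize_front(pts)
  for (i in 1:10) for (j in 1:10) {
    if (i == j) next
    dom_raw <- all(pts[i, ] <= pts[j, ]) && any(pts[i, ] < pts[j, ])
    dom_norm <- all(norm[i, ] <= norm[j, ]) && any(norm[i, ] < norm[j, ])
    expect_equal(dom_raw, dom_norm)
  }
  # maximisation coordinates are negated before scaling
  mx <- normalize_front(rbind(c(1, 5), c(3, 5)), c("max", "min"))
  expect_equal(mx[, 1L], c(1, 0))
})

test_that("2-D hypervolume computes the union area of dominated rectangles", {
  expect_equal(hypervolume_2d(rbind(c(0.5, 0.5))), 0.25)
  expect_equal(hypervolume_2d(NULL), 0)
  # union of [0.2,1]x[0.8,1] and [0.6,1]x[0.3,1]: 0.16 + 0.28 - 0.08 overlap
  expect_equal(hypervolume_2d(rbind(c(0.2, 0.8), c(0.6, 0.3))), 0.36)
  # dominated points contribute nothing; adding points never decreases it
  base <- rbind(c(0.3, 0.4))
  expect_equal(hypervolume_2d(rbind(base, c(0.5, 0.5))),
               hypervolume_2d(base))
  expect_gte(hypervolume_2d(rbind(base, c(0.1, 0.9))),
             hypervolume_2d(base))
  expect_error(hypervolume_2d(rbind(c(-0.1, 0.5))), "within")
})

test_that("hypervolume matches the Monte-Carlo oracle on random fronts", {
  set.seed(17)
  for (rep in 1:5) {
    pts <- matrix(runif(2L * sample(2:6, 1L)), ncol = 2L)
    hv <- hypervolume_2d(pts)
    mc <- mc_hypervolume(pts, 2e5)
    expect_equal(hv, mc, tolerance = 0.01)
  }
})

test_that("shared normalisation makes hypervolumes comparable across fronts", {
  f1 <- rbind(c(1, 3), c(2, 2), c(3, 1))
  f2 <- rbind(c(2, 4), c(4, 2))
  hv <- hypervolume_compare(list(f1, f2))
  expect_length(hv, 2L)
  expect_gt(hv[1L], hv[2L])   # f1 dominates f2 everywhere
})

test_that("single-solution selection maximises expression silhouette", {
  d <- small_distances()
  cfg <- run_config(K = 3L, pop_size = 10L, generations = 2L, seed = 14L,
                    sga_pop = 10L, sga_generations = 2L)
  fr <- evolve(cfg, d$D_EB, d$D_BB)
  sel <- select_single_solution(fr, d$D_EB)
  sils <- vapply(fr$chromosomes, function(ch)
    silhouette_index(d$D_EB, assign_to_medoids(d$D_EB, ch)), numeric(1L))
  expect_equal(sel$silhouette, max(sils))
  expect_equal(sort(sel$partition$medoids), sort(sel$chromosome))
  # front of one returns that solution
  fr1 <- fr
  fr1$chromosomes <- fr$chromosomes[1L]
  fr1$objectives <- fr$objectives[1L, , drop = FALSE]
  expect_equal(select_single_solution(fr1, d$D_EB)$chromosome,
               sort(fr$chromosomes[[1L]]))
})

test_that("Friedman test matches stats::friedman.test and handles ties", {
  set.seed(19)
  for (rep in 1:5) {
    tab <- matrix(runif(12), 4L, 3L)
    ours <- friedman_test(tab)
    ref <- stats::friedman.test(tab)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  # a column that always wins has mean rank 1
  tab <- cbind(best = c(9, 9, 9), mid = c(5, 4, 6), low = c(1, 2, 3))
  expect_equal(unname(friedman_test(tab)$mean_ranks), c(1, 2, 3))
  # all-constant table: statistic 0, p 1
  flat <- matrix(1, 3L, 3L)
  ft <- friedman_test(flat)
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p_value, 1)
  # min-rank convention assigns tied scores their group minimum
  tied <- rbind(c(3, 2, 2), c(3, 2, 1))
  expect_equal(unname(friedman_test(tied, tie_method = "min")$ranks[1L, ]),
               c(1, 2, 2))
  expect_equal(unname(friedman_test(tied)$ranks[1L, ]), c(1, 2.5, 2.5))
})

test_that("chi-square Friedman p is close to the exact permutation null", {
  tab <- rbind(c(1.0, 0.6, 0.2), c(0.9, 0.5, 0.4), c(0.8, 0.1, 0.3))
  ours <- friedman_test(tab)
  # enumerate all (3!)^3 within-row rank permutations for the exact null
  perms <- as.matrix(expand.grid(1:6, 1:6, 1:6))
  all_orders <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                      c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  stat_of <- function(r) {
    12 * sum((colSums(r) - 3 * 4 / 2)^2) / (3 * 3 * 4)
  }
  null_stats <- apply(perms, 1L, function(idx)
    stat_of(rbind(all_orders[idx[1L], ], all_orders[idx[2L], ],
                  all_orders[idx[3L], ])))
  exact_p <- mean(null_stats >= stat_of(ours$ranks) - 1e-12)
  expect_equal(ours$ranks, t(apply(-tab, 1L, rank)), ignore_attr = TRUE)
  # chi-square approximation is coarse at n = k = 3; just require agreement
  # within its known accuracy
  expect_lt(abs(ours$p_value - exact_p), 0.12)
})

test_that("enrichment p-values equal the hypergeometric tail", {
  expect_equal(enrichment_pvalue(0, 4, 5, 10), 1)
  expect_equal(enrichment_pvalue(4, 4, 5, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(enrichment_pvalue(6, 6, 5, 10), 0)
  # matches a direct sum of binomial-coefficient terms
  brute <- function(k, n, f, g) {
    i <- 0:(k - 1)
    1 - sum(choose(f, i) * choose(g - f, n - i)) / choose(g, n)
  }
  for (k in 1:4)
    expect_equal(enrichment_pvalue(k, 6, 8, 20), brute(k, 6, 8, 20),
                 tolerance = 1e-12)
  # non-increasing in k
  ps <- vapply(0:6, enrichment_pvalue, numeric(1L), n = 6, f = 8, g = 20)
  expect_true(all(diff(ps) <= 1e-15))
})
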