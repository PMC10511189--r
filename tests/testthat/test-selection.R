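test_that("greedy selection matches brute force on the toy tree", {
  tr <- toy_tree()
  res <- greedy_max_pd(tr, k = 2, seed = 1)
  expect_equal(res$pd_value, 5)  # brute force over all 6 pairs gives max 5
  expect_true(setequal(intersect(res$taxa, c("A", "B")), res$taxa[res$taxa %in% c("A", "B")]))
  # one tip from each cherry
  expect_length(intersect(res$taxa, c("A", "B")), 1L)
  expect_length(intersect(res$taxa, c("C", "D")), 1L)
  expect_equal(greedy_max_pd(tr, k = 4, seed = 1)$pd_value, 7)
  # secured baseline: gain on top of {C,D}; either A or B adds 2
  res2 <- greedy_max_pd(tr, universe = c("A", "B"), k = 1,
                        secured = c("C", "D"), seed = 1)
  expect_true(res2$taxa %in% c("A", "B"))
  expect_equal(res2$pd_value, 6)
  expect_error(greedy_max_pd(tr, universe = c("A", "B"), k = 3), "between 1")
})

test_that("greedy equals exhaustive-search max PD on random small trees", {
  # greedy PD maximization is exact on trees; checked against an
  # independent brute-force oracle (scaled-down version of the full
  # acceptance sweep)
  for (seed in 1:25) {
    tr <- random_tree(sample(6:10, 1), seed)
    n <- length(tr$tip.label)
    for (k in seq_len(n)) {
      g <- greedy_max_pd(tr, k = k, seed = seed)
      expect_equal(g$pd_value, brute_force_max_pd(tr, k), tolerance = 1e-9)
    }
  }
})

test_that("greedy covers the whole tree at k = n and respects secured overlap", {
  tr <- random_tree(12, 3)
  g <- greedy_max_pd(tr, k = 12, seed = 1)
  expect_equal(g$pd_value, sum(tr$edge.length))
  # secured species are removed from the candidate universe
  g2 <- greedy_max_pd(tr, universe = tr$tip.label, k = 11,
                      secured = tr$tip.label[1], seed = 1)
  expect_false(tr$tip.label[1] %in% g2$taxa)
  expect_equal(g2$pd_value, sum(tr$edge.length))
})

test_that("greedy tie-breaks are seeded and produce replicate set variety", {
  # on an ultrametric tree every first pick is tied; distinct seeds must
  # explore distinct optima while keeping PD identical
  tr <- simulate_yule_tree(30, 1, seed = 2)
  res <- lapply(1:10, function(r) greedy_max_pd(tr, k = 5, seed = r))
  pds <- vapply(res, `[[`, numeric(1), "pd_value")
  expect_equal(max(pds) - min(pds), 0, tolerance = 1e-9)
  sets <- vapply(res, function(r) paste(sort(r$taxa), collapse = "|"), "")
  expect_gt(length(unique(sets)), 1L)
  expect_identical(greedy_max_pd(tr, k = 5, seed = 7)$taxa,
                   greedy_max_pd(tr, k = 5, seed = 7)$taxa)
})

test_that("greedy_over_ensemble produces sets_per_tree x n_trees results deterministically", {
  ens <- simulate_yule_ensemble(20, 3, seed = 6)
  out <- greedy_over_ensemble(ens, fraction = 0.25, sets_per_tree = 4, seed = 9)
  expect_length(out, 12L)
  expect_true(all(vapply(out, `[[`, integer(1), "n_selected") == 5L))
  expect_equal(vapply(out, `[[`, integer(1), "tree_index"),
               rep(1:3, each = 4))
  out2 <- greedy_over_ensemble(ens, fraction = 0.25, sets_per_tree = 4, seed = 9)
  expect_identical(lapply(out, `[[`, "taxa"), lapply(out2, `[[`, "taxa"))
  one <- greedy_over_ensemble(tree_ensemble(ens$trees[[1]]), fraction = 0.5,
                              sets_per_tree = 1, seed = 2)
  expect_length(one, 1L)
})

test_that("sample-size rounding is half-up", {
  ens <- simulate_yule_ensemble(10, 1, seed = 1)
  # 0.25 * 10 = 2.5 -> 3 under half-up
  out <- greedy_over_ensemble(ens, fraction = 0.25, sets_per_tree = 1, seed = 1)
  expect_equal(out[[1]]$n_selected, 3L)
  expect_equal(pdoption:::round_half_up(c(2.5, 2.49, 74.5, -0.2)),
               c(3L, 2L, 75L, 0L))
})

test_that("rank selection is deterministic with lexicographic tie-breaking", {
  expect_setequal(rank_select(c(A = 3, B = 2, C = 1), k = 2)$taxa, c("A", "B"))
  expect_identical(rank_select(c(B = 1, A = 1, C = 1), k = 1)$taxa, "A")
  u <- c("A", "B", "C")
  expect_setequal(rank_select(c(A = 1, B = 2, C = 3), u, k = 3)$taxa, u)
  expect_error(rank_select(c(A = 1), universe = c("A", "B"), k = 1), "B")
})

test_that("weighted sampling follows the sequential-draw law", {
  # equal weights: uniform first-draw frequencies
  u <- c("a", "b", "c", "d")
  draws <- vapply(1:10000, function(r) {
    sample_weighted(u, 1, k = 1, seed = r)$taxa
  }, "")
  freq <- table(draws) / 10000
  expect_true(all(freq >= 0.22 & freq <= 0.28))
  # VU vs CR with Red List Index weights 2 and 4: CR first-drawn 2/3
  draws2 <- vapply(1:10000, function(r) {
    sample_weighted(c("vuSp", "crSp"), c(vuSp = 2, crSp = 4),
                    k = 1, seed = 20000 + r)$taxa
  }, "")
  expect_lt(abs(mean(draws2 == "crSp") - 2 / 3), 0.02)
  # k = |universe| returns everything regardless of weights
  expect_setequal(sample_weighted(u, c(a = 1, b = 100, c = 1, d = 1),
                                  k = 4, seed = 1)$taxa, u)
  expect_error(sample_weighted(u, c(a = 1, b = 0, c = 1, d = 1), k = 2, seed = 1),
               "positive")
})

test_that("Red List Index weights follow the published ladder", {
  expect_equal(rl_index_weight(c("VU", "EN", "CR", "EW")), c(2, 3, 4, 5))
  expect_error(rl_index_weight("LC"), "LC")
})

test_that("RL-controlled sampling reproduces the template category histogram exactly", {
  with_seed_test(1, {
    n <- 60
    sp <- sprintf("s%02d", 1:n)
    rl <- setNames(sample(c("VU", "EN", "CR"), n, replace = TRUE), sp)
    template <- c(sp[rl == "CR"][1:2], sp[rl == "EN"][1:3])
    for (r in 1:50) {
      res <- sample_rl_controlled(sp, rl, template, seed = r)
      expect_equal(sort(as.vector(table(rl[res$taxa]))), c(2L, 3L),
                   ignore_attr = TRUE)
      expect_equal(unname(table(rl[res$taxa])[c("CR", "EN")]), c(2L, 3L),
                   ignore_attr = TRUE)
    }
    # template = whole universe -> the whole universe comes back
    res_all <- sample_rl_controlled(sp, rl, sp, seed = 1)
    expect_setequal(res_all$taxa, sp)
    # infeasible: template needs more CR than the universe holds
    tiny <- sp[1:5]
    rl_tiny <- setNames(c("CR", "VU", "VU", "VU", "VU"), tiny)
    expect_error(
      sample_rl_controlled(tiny, rl_tiny, tiny[c(1, 1)], seed = 1),
      "CR")
  })
})
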