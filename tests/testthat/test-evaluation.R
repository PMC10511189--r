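test_that("capture counting uses flag intersections and union semantics for 'all'", {
  tab <- make_table(LETTERS[1:6], food = c("B", "C"), pets = c("A"))
  expect_equal(count_captured(c("A", "B"), tab, "food"), 1L)
  expect_equal(count_captured(c("A", "B"), tab, "all"), 2L)
  expect_equal(count_captured(c("E", "F"), tab, "food"), 0L)
  # 'other' joins 'all' only on request
  tab2 <- make_table(LETTERS[1:6], food = "B", other = "D")
  expect_equal(count_captured(LETTERS[1:6], tab2, "all"), 1L)
  expect_equal(count_captured(LETTERS[1:6], tab2, "all", include_other = TRUE), 2L)
  expect_error(flagged_species(tab, "fuel"), "unknown")
})

test_that("capture summaries carry empirical 95% CIs that bracket the mean", {
  tab <- make_table(sprintf("s%02d", 1:40), food = sprintf("s%02d", 1:10))
  sets <- lapply(1:200, function(r) {
    sample_weighted(tab$species, 1, k = 8, seed = r, strategy = "random_uniform")
  })
  cs <- capture_summary(sets, tab, "food")
  expect_equal(cs$mean, mean(cs$counts))
  expect_lte(cs$ci95_low, cs$mean)
  expect_gte(cs$ci95_high, cs$mean)
  expect_true(all(cs$counts >= 0 & cs$counts <= 10))
  # E[capture] = 8 * 10/40 = 2
  expect_equal(cs$mean, 2, tolerance = 0.35)
})

test_that("ses_between computes SES with the documented sign and guards", {
  tab <- make_table(LETTERS[1:4], food = "A")
  mk <- function(counts, strategy) {
    sets <- lapply(seq_along(counts), function(i) {
      r <- if (counts[i] == 1) "A" else "B"
      res <- pdoption:::new_selection_result(strategy, r, fraction = 0.25)
      res
    })
    capture_summary(sets, tab, "food")
  }
  obs <- mk(c(1, 1, 1, 1), "greedy_pd")
  null <- mk(c(1, 0, 0, 1), "random_uniform")
  rep <- ses_between(obs, null)
  expect_equal(rep$m_obs, 1)
  expect_equal(rep$m_null, 0.5)
  expect_equal(rep$ses, (1 - 0.5) / sd(c(1, 0, 0, 1)))
  # sign flips when observed falls below the null
  rep2 <- ses_between(mk(c(0, 0, 0, 0), "edge_rank"), null)
  expect_lt(rep2$ses, 0)
  expect_error(ses_between(null, mk(c(1, 1), "random_uniform")), "degenerate")
})

test_that("order overrepresentation flags a fully-loaded small order as over", {
  # 10 species, order X = exactly the 2 flagged species:
  # P(random 2-subset == X's 2 species) = 1/C(10,2) = 1/45 < 0.025
  tab <- make_table(sprintf("s%02d", 1:10),
                    orders = c("X", "X", rep("Y", 8)),
                    food = c("s01", "s02"))
  rep <- order_overrepresentation(tab, "food", n_perm = 999, seed = 42)
  expect_equal(rep$verdict[rep$order == "X"], "over")
  expect_equal(rep$observed[rep$order == "X"], 2L)
})

test_that("an order containing every species is never flagged", {
  tab <- make_table(sprintf("s%02d", 1:10), orders = rep("Z", 10),
                    food = sprintf("s%02d", 1:3))
  rep <- order_overrepresentation(tab, "food", n_perm = 199, seed = 1)
  expect_equal(rep$verdict, "ns")
})

test_that("order test is reproducible and errors on empty categories", {
  tab <- make_table(sprintf("s%02d", 1:30),
                    orders = rep(c("X", "Y", "Z"), each = 10),
                    food = sprintf("s%02d", 1:4))
  r1 <- order_overrepresentation(tab, "food", n_perm = 99, seed = 5)
  r2 <- order_overrepresentation(tab, "food", n_perm = 99, seed = 5)
  expect_identical(r1$verdict, r2$verdict)
  expect_error(order_overrepresentation(tab, "medicine", 99, 1), "no species")
})

test_that("top-set overlap handles identity, antitone and random scores", {
  sp <- sprintf("s%03d", 1:100)
  sc <- setNames(seq_along(sp), sp)
  ov_same <- top_set_overlap(sc, sc, fraction = 0.05)
  expect_equal(ov_same$n_both, ov_same$k)
  ov_anti <- top_set_overlap(sc, -sc, fraction = 0.05)
  expect_equal(ov_anti$n_both, 0L)
  expect_equal(ov_anti$n_a_only, ov_anti$k)
  # invariant: |a_only| + |both| = k on random scores
  with_seed_test(8, {
    for (r in 1:10) {
      ov <- top_set_overlap(setNames(rnorm(100), sp), setNames(rnorm(100), sp),
                            fraction = 0.1)
      expect_equal(length(ov$a_only) + length(ov$both), ov$k)
      expect_equal(length(ov$b_only) + length(ov$both), ov$k)
    }
  })
})

test_that("mean overlap of independent scores matches the hypergeometric k^2/N", {
  # scaled-down version of the acceptance check: N = 200, k = 10,
  # E|both| = k^2/N = 0.5
  sp <- sprintf("s%03d", 1:200)
  with_seed_test(21, {
    ovs <- vapply(1:400, function(r) {
      top_set_overlap(setNames(rnorm(200), sp), setNames(rnorm(200), sp),
                      fraction = 0.05)$n_both
    }, numeric(1))
    expect_equal(mean(ovs), 0.5, tolerance = 0.12)
  })
})

test_that("Dunn z agrees with Kruskal-Wallis in the two-group case", {
  # with two groups the Kruskal-Wallis statistic equals the squared Dunn z
  with_seed_test(3, {
    for (r in 1:5) {
      x <- c(rnorm(12), rnorm(15, mean = 0.8))
      g <- rep(c("a", "b"), c(12, 15))
      d <- dunn_test(x, g)
      k <- kruskal.test(x, factor(g))
      expect_equal(d$z^2, unname(k$statistic), tolerance = 1e-10)
    }
    # tie correction: duplicated values still match
    x2 <- round(c(rnorm(20), rnorm(20, 1)), 1)
    g2 <- rep(c("a", "b"), each = 20)
    expect_equal(dunn_test(x2, g2)$z^2,
                 unname(kruskal.test(x2, factor(g2))$statistic),
                 tolerance = 1e-10)
  })
})

test_that("distinctiveness statistics: identical samples and exact correlations", {
  tab <- make_table(sprintf("s%02d", 1:40),
                    food = sprintf("s%02d", 1:10),
                    pets = sprintf("s%02d", 11:20),
                    materials = sprintf("s%02d", 21:26))
  ed <- setNames(seq_len(40) / 10, tab$species)
  tab$fdist <- as.numeric(ed)  # fdist == ed exactly
  res <- compare_distinctiveness(tab, ed)
  expect_equal(unname(res$pearson$estimate), 1)
  expect_s3_class(res$kruskal, "htest")
  expect_true(all(c("z", "p_adj") %in% names(res$dunn)))
  expect_equal(nrow(res$dunn), 3L)  # 3 pairwise comparisons among 3 categories
  # Welch on two identical samples: t = 0, p = 1
  tt <- t.test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(unname(tt$statistic), 0)
  expect_equal(tt$p.value, 1)
  expect_error(compare_distinctiveness(tab, ed, categories = c("food", "medicine")),
               "two non-empty")
})

test_that("Kruskal-Wallis type-I error is calibrated at the nominal level", {
  # three groups from one distribution: rejection rate ~ 5%
  with_seed_test(13, {
    rejections <- vapply(1:1000, function(r) {
      x <- rnorm(90)
      g <- rep(c("a", "b", "c"), each = 30)
      kruskal.test(x, factor(g))$p.value < 0.05
    }, logical(1))
    expect_lt(abs(mean(rejections) - 0.05), 0.015)
  })
})
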