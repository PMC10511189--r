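test_that("Yule trees are valid, ultrametric, binary and deterministic per seed", {
  tr <- simulate_yule_tree(2, 1, seed = 5)
  expect_length(tr$tip.label, 2L)
  d <- ape::node.depth.edgelength(tr)
  expect_equal(d[1], d[2])  # a cherry: equal root-to-tip distances
  tr50a <- simulate_yule_tree(50, 1, seed = 123)
  tr50b <- simulate_yule_tree(50, 1, seed = 123)
  expect_identical(ape::write.tree(tr50a), ape::write.tree(tr50b))
  expect_false(identical(ape::write.tree(tr50a),
                         ape::write.tree(simulate_yule_tree(50, 1, seed = 124))))
  expect_true(ape::is.ultrametric(tr50a, tol = 1e-8))
  expect_true(ape::is.binary(tr50a))
  expect_true(ape::is.rooted(tr50a))
  expect_equal(tr50a$Nnode, 49L)  # n - 1 internal nodes, every tree
  expect_error(simulate_yule_tree(1), "at least 2")
})

test_that("Yule depth matches the pure-birth closed form within 3 SE", {
  # E[depth] = sum_{k=2}^{n} 1/(lambda k); independent closed-form oracle
  n <- 100; reps <- 300
  depths <- vapply(seq_len(reps), function(i) {
    tr <- simulate_yule_tree(n, 1, seed = 7000 + i)
    max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  expected <- sum(1 / (2:n))
  se <- sd(depths) / sqrt(reps)
  expect_lt(abs(mean(depths) - expected), 3 * se)
})

test_that("use labels hit the exact quota and respect the clumping knob", {
  tr <- simulate_yule_tree(100, 1, seed = 31)
  expect_setequal(simulate_use_labels(tr, 1, 0, 1), tr$tip.label)
  expect_identical(simulate_use_labels(tr, 0, 0, 1), character(0))
  for (prev in c(0.02, 0.1, 0.35)) {
    for (cl in c(0, 0.5, 1)) {
      lab <- simulate_use_labels(tr, prev, cl, seed = 17)
      expect_length(lab, round(prev * 100))
      expect_true(all(lab %in% tr$tip.label))
    }
  }
  # clumping = 1 returns tips of one clade (monophyletic up to trimming):
  # their PD is far below that of the same number of uniform tips
  lab1 <- simulate_use_labels(tr, 0.1, 1, seed = 17)
  lab0 <- simulate_use_labels(tr, 0.1, 0, seed = 17)
  expect_lt(pd(tr, lab1), pd(tr, lab0))
  expect_error(simulate_use_labels(tr, 1.2, 0, 1), "prevalence")
  expect_error(simulate_use_labels(tr, 0.5, -1, 1), "clumping")
})

test_that("clumped labels read as clumped; uniform labels calibrate to SES 0", {
  # fixed 100-tip tree; moderate replicate count for the unit suite (the
  # acceptance suite runs the full-size calibration)
  ens <- tree_ensemble(simulate_yule_tree(100, 1, seed = 41))
  ses0 <- vapply(1:60, function(r) {
    lab <- simulate_use_labels(ens$trees[[1]], 0.1, 0, seed = 5000 + r)
    dispersion_ses(ens, lab, n_shuffles = 200, seed = 6000 + r)$ses
  }, numeric(1))
  expect_lt(abs(mean(ses0)), 3 * sd(ses0) / sqrt(length(ses0)) + 0.15)
  ses1 <- vapply(1:20, function(r) {
    tr <- simulate_yule_tree(100, 1, seed = 8000 + r)
    lab <- simulate_use_labels(tr, 0.1, 1, seed = 100 + r)
    dispersion_ses(tree_ensemble(tr), lab, n_shuffles = 200,
                   seed = 9000 + r)$ses
  }, numeric(1))
  expect_gte(mean(ses1 < -1.96), 0.95)
})

test_that("synth_config validates its fields", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(rl_proportions = c(LC = 0.5, NT = 0.4)), "sum to 1")
  expect_error(synth_config(prevalence = c(food = 1.5, materials = 0,
                                           medicine = 0, pets = 0, other = 0)),
               "prevalence")
  expect_error(synth_config(fdist_ed_corr = 2), "fdist_ed_corr")
  expect_error(synth_config(n_tips = 1), "n_tips")
})

test_that("attribute tables honor Red List proportions and label quotas", {
  cfg <- synth_config(n_tips = 2000, n_trees = 1, seed = 77)
  ens <- simulate_yule_ensemble(cfg$n_tips, 1, seed = cfg$seed)
  tab <- simulate_attributes(ens, cfg)
  expect_equal(nrow(tab), 2000L)
  # Kolmogorov distance between realized and configured category fractions
  realized <- table(factor(tab$rl_category, levels = RL_CATEGORIES)) / 2000
  expect_lt(max(abs(cumsum(as.numeric(realized)) -
                    cumsum(as.numeric(cfg$rl_proportions)))), 0.05)
  for (categ in c("food", "materials", "medicine", "pets", "other")) {
    expect_length(flagged_species(tab, categ),
                  round(cfg$prevalence[[categ]] * 2000))
  }
  # all-LC degenerate composition
  cfg_lc <- synth_config(n_tips = 50, n_trees = 1,
                         rl_proportions = c(LC = 1), seed = 3)
  out <- generate_synthetic_data(cfg_lc)
  expect_true(all(out$table$rl_category == "LC"))
})

test_that("FDist hits the target ED correlation exactly, including the identity case", {
  cfg <- synth_config(n_tips = 500, n_trees = 2, fdist_ed_corr = 0.11, seed = 19)
  out <- generate_synthetic_data(cfg)
  ed <- ed_table(out$ensemble)
  ed_med <- ed$ed_median[match(out$table$species, ed$species)]
  r <- cor(out$table$fdist, ed_med)
  expect_true(r >= 0.06 && r <= 0.16)
  expect_equal(r, 0.11, tolerance = 1e-8)
  cfg1 <- synth_config(n_tips = 100, n_trees = 1, fdist_ed_corr = 1, seed = 19)
  out1 <- generate_synthetic_data(cfg1)
  ed1 <- ed_table(out1$ensemble)
  ed_med1 <- ed1$ed_median[match(out1$table$species, ed1$species)]
  expect_equal(cor(out1$table$fdist, ed_med1, method = "spearman"), 1)
  expect_true(all(out1$table$fdist >= 0))
})

test_that("identical configs give byte-identical outputs on disk", {
  cfg <- synth_config(n_tips = 30, n_trees = 2, seed = 55)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_synthetic_data(cfg, out_dir = d1)
  generate_synthetic_data(cfg, out_dir = d2)
  for (f in c("trees.nwk", "species.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # and the written files round-trip through the readers
  ens <- read_tree_ensemble(file.path(d1, "trees.nwk"))
  tab <- read_species_table(file.path(d1, "species.csv"))
  expect_setequal(ens$shared_tipset, tab$species)
})
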