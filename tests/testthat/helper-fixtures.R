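# Shared fixtures, built in code at test time.

# the worked toy tree: ((A:1,B:1):1,(C:1,D:1):2);
toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):2);")
}

toy_newick <- "((A:1,B:1):1,(C:1,D:1):2);"

# small species table consistent with the toy tree
toy_table <- function() {
  data.frame(
    species = c("A", "B", "C", "D"),
    order = c("O1", "O1", "O2", "O2"),
    rl_category = c("LC", "VU", "EN", "CR"),
    use_food = c(0, 1, 1, 0),
    use_materials = c(0, 0, 0, 1),
    use_medicine = c(0, 0, 0, 0),
    use_pets = c(1, 0, 0, 0),
    use_other = c(0, 0, 0, 0),
    fdist = c(0.1, 0.4, 0.2, 0.9),
    stringsAsFactors = FALSE
  )
}

# random tree with exponential branch lengths (not ultrametric), for
# property tests that must not rely on ultrametricity
random_tree <- function(n, seed) {
  tr <- with_seed_test(seed, {
    tr <- ape::rtree(n)
    tr$edge.length <- rexp(nrow(tr$edge), rate = 2) + 1e-6
    tr
  })
  tr
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# exhaustive-search maximum PD over all k-subsets (independent oracle for
# the greedy algorithm)
brute_force_max_pd <- function(tree, k) {
  tips <- tree$tip.label
  subsets <- utils::combn(tips, k, simplify = FALSE)
  max(vapply(subsets, function(s) pd(tree, s), numeric(1)))
}

# a synthetic species table over given species ids with controllable flags
make_table <- function(species, orders = NULL, rl = "LC",
                       food = character(0), materials = character(0),
                       medicine = character(0), pets = character(0),
                       other = character(0), fdist = NULL) {
  n <- length(species)
  if (is.null(orders)) orders <- rep("O1", n)
  if (length(rl) == 1L) rl <- rep(rl, n)
  if (is.null(fdist)) fdist <- seq_len(n) / n
  data.frame(
    species = species, order = orders, rl_category = rl,
    use_food = species %in% food,
    use_materials = species %in% materials,
    use_medicine = species %in% medicine,
    use_pets = species %in% pets,
    use_other = species %in% other,
    fdist = fdist,
    stringsAsFactors = FALSE
  )
}
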