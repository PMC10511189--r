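# Species-set selection strategies: greedy PD maximization (optionally on
# top of a "secured" baseline of low-risk species), rank-based prioritization
# (EDGE / ED / FDist), and the stochastic null strategies (uniform random,
# Red-List-weighted, Red-List-controlled, FDist-weighted sampling).

SELECTION_STRATEGIES <- c("greedy_pd", "greedy_pd_threatened", "edge_rank",
                          "ed_rank", "fdist_rank", "random_uniform",
                          "rl_weighted", "rl_controlled", "fdist_weighted")

new_selection_result <- function(strategy, taxa, fraction = NA_real_,
                                 tree_index = NA_integer_,
                                 replicate = NA_integer_,
                                 pd_value = NA_real_) {
  structure(
    list(strategy = strategy, fraction = fraction,
         n_selected = length(taxa), tree_index = tree_index,
         replicate = replicate, taxa = taxa, pd_value = pd_value),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<%s> %d species%s%s\n", x$strategy, x$n_selected,
              if (is.na(x$fraction)) "" else sprintf(" (fraction %.3g)", x$fraction),
              if (is.na(x$pd_value)) "" else sprintf(", PD = %.4g", x$pd_value)))
  invisible(x)
}

#' Greedy PD-maximizing species selection
#'
#' Builds a species set of size `k` that maximizes rooted Faith PD by greedy
#' forward selection: at each step the candidate whose addition yields the
#' largest PD increment over the already-covered subtree is added. On a tree
#' this greedy procedure attains the global optimum for every `k`. A
#' `secured` baseline set (e.g. low-risk species assumed safe from
#' extinction) can be supplied: its subtree counts as already covered, so
#' the algorithm maximizes the PD *gain* on top of it. Ties in the PD
#' increment are broken uniformly at random with the seeded generator — on
#' ultrametric trees the first pick is always tied across all tips, which is
#' what makes replicate PD-maximizing sets differ.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param universe candidate species (tip labels); defaults to all tips not
#'   in `secured`.
#' @param k number of species to select, `1 <= k <= |universe|`.
#' @param secured species whose subtree is treated as already conserved.
#'   Any overlap with `universe` is removed from the candidates.
#' @param seed integer seed driving tie-breaks.
#' @return a `selection_result` whose `pd_value` is
#'   `pd(tree, secured + selected)`.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):2);")
#' res <- greedy_max_pd(tr, k = 2, seed = 1)
#' res$pd_value  # 5
greedy_max_pd <- function(tree, universe = NULL, k, secured = character(0),
                          seed = 1L) {
  tree <- validate_phylogeny(tree)
  idx <- tree_index(tree)
  if (is.null(universe)) {
    universe <- setdiff(idx$tip_labels, normalize_label(secured))
  }
  universe <- unique(normalize_label(universe))
  secured <- unique(normalize_label(secured))
  universe <- setdiff(universe, secured)
  cand <- match_taxa(universe, idx$tip_labels)
  if (k < 1L || k > length(cand)) {
    stop(sprintf("k must be between 1 and |universe| = %d", length(cand)))
  }
  unused <- rep(TRUE, length(idx$edge_length))
  if (length(secured) > 0L) {
    sec_idx <- match_taxa(secured, idx$tip_labels)
    unused[unique(unlist(idx$paths[sec_idx]))] <- FALSE
  }
  base_pd <- sum(idx$edge_length[!unused])
  selected <- integer(k)
  with_seed(derive_seed(seed, 61L), {
    remaining <- cand
    for (step in seq_len(k)) {
      len_unused <- idx$edge_length * unused
      gains <- vapply(remaining, function(tip) sum(len_unused[idx$paths[[tip]]]),
                      numeric(1))
      best <- max(gains)
      ties <- which(gains >= best - 1e-12 * max(1, abs(best)))
      pick <- if (length(ties) == 1L) ties else ties[sample.int(length(ties), 1L)]
      tip <- remaining[pick]
      selected[step] <- tip
      unused[idx$paths[[tip]]] <- FALSE
      base_pd <- base_pd + gains[pick]
      remaining <- remaining[-pick]
    }
  })
  new_selection_result("greedy_pd", taxa = idx$tip_labels[selected],
                       pd_value = base_pd)
}

#' Replicated greedy PD maximization over a tree ensemble
#'
#' Runs [greedy_max_pd()] `sets_per_tree` times on every tree of the
#' ensemble with distinct derived seeds, yielding
#' `length(ensemble) * sets_per_tree` PD-maximizing sets of identical size
#' `round_half_up(fraction * |universe|)`.
#'
#' @param ensemble a [tree_ensemble()].
#' @param universe candidate species; defaults to all shared tips not in
#'   `secured`.
#' @param fraction sample size as a fraction of the universe, in `(0, 1]`.
#' @param sets_per_tree replicate sets per tree (>= 1).
#' @param secured species treated as already conserved.
#' @param seed master seed.
#' @param strategy label stored on the results.
#' @return list of `selection_result` objects.
#' @export
greedy_over_ensemble <- function(ensemble, universe = NULL, fraction,
                                 sets_per_tree = 10L, secured = character(0),
                                 seed = 1L, strategy = "greedy_pd") {
  stopifnot(inherits(ensemble, "tree_ensemble"), sets_per_tree >= 1L)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (is.null(universe)) {
    universe <- setdiff(ensemble$shared_tipset, normalize_label(secured))
  }
  universe <- setdiff(unique(normalize_label(universe)),
                      normalize_label(secured))
  k <- max(1L, round_half_up(fraction * length(universe)))
  out <- vector("list", length(ensemble$trees) * sets_per_tree)
  pos <- 0L
  for (t in seq_along(ensemble$trees)) {
    for (r in seq_len(sets_per_tree)) {
      res <- greedy_max_pd(ensemble$trees[[t]], universe = universe, k = k,
                           secured = secured,
                           seed = derive_seed(seed, 71L, t, r))
      res$strategy <- strategy
      res$fraction <- fraction
      res$tree_index <- t
      res$replicate <- r
      pos <- pos + 1L
      out[[pos]] <- res
    }
  }
  out
}

#' Deterministic top-k selection by score rank
#'
#' Selects the `k` highest-scoring species; ties are broken by species id in
#' lexicographic order, so a published ranking always maps to one set.
#'
#' @param scores named numeric vector (names = species ids) covering the
#'   whole universe.
#' @param universe candidate species; defaults to `names(scores)`.
#' @param k number to select.
#' @param strategy label stored on the result.
#' @return a `selection_result`.
#' @export
rank_select <- function(scores, universe = NULL, k,
                        strategy = "rank") {
  if (is.null(universe)) universe <- names(scores)
  universe <- unique(normalize_label(universe))
  names(scores) <- normalize_label(names(scores))
  missing <- setdiff(universe, names(scores))
  if (length(missing) > 0L) {
    stop(sprintf("no score for species: %s", paste(missing, collapse = ", ")))
  }
  if (k < 1L || k > length(universe)) {
    stop(sprintf("k must be between 1 and |universe| = %d", length(universe)))
  }
  s <- scores[universe]
  ord <- order(-s, universe)
  new_selection_result(strategy, taxa = universe[ord][seq_len(k)])
}

#' Weighted sampling of species without replacement
#'
#' Draws `k` species sequentially, each draw with probability proportional
#' to its weight among the species still available — e.g. Red List Index
#' weights (VU = 2, EN = 3, CR = 4, EW = 5) for an extinction-risk-weighted
#' strategy, or FDist scores for a functional-distinctiveness-weighted one.
#' Equal weights reduce to uniform sampling without replacement.
#'
#' @param universe candidate species ids.
#' @param weights positive numeric vector, either named by species or in
#'   `universe` order; a single value is recycled (uniform sampling).
#' @param k number to draw.
#' @param seed integer seed.
#' @param strategy label stored on the result.
#' @return a `selection_result`.
#' @export
sample_weighted <- function(universe, weights = 1, k, seed = 1L,
                            strategy = "weighted") {
  universe <- unique(normalize_label(universe))
  if (length(weights) == 1L) weights <- rep(weights, length(universe))
  if (!is.null(names(weights))) {
    names(weights) <- normalize_label(names(weights))
    missing <- setdiff(universe, names(weights))
    if (length(missing) > 0L) {
      stop(sprintf("no weight for species: %s",
                   paste(missing, collapse = ", ")))
    }
    weights <- weights[universe]
  }
  if (length(weights) != length(universe)) {
    stop("weights must match the universe")
  }
  if (anyNA(weights) || any(weights <= 0)) {
    stop("all weights must be positive")
  }
  if (k < 1L || k > length(universe)) {
    stop(sprintf("k must be between 1 and |universe| = %d", length(universe)))
  }
  taxa <- with_seed(derive_seed(seed, 83L), {
    universe[sample.int(length(universe), k, prob = weights)]
  })
  new_selection_result(strategy, taxa = taxa)
}

#' Red List weights for the risk-weighted sampling strategy
#'
#' Red List Index category weights used as selection probabilities for
#' threatened species: VU = 2, EN = 3, CR = 4, EW = 5.
#'
#' @param rl_category character vector of threatened Red List categories.
#' @return numeric weights.
#' @export
rl_index_weight <- function(rl_category) {
  map <- c(VU = 2, EN = 3, CR = 4, EW = 5)
  rl_category <- toupper(trimws(rl_category))
  bad <- !(rl_category %in% names(map))
  if (any(bad)) {
    stop(sprintf("no Red List Index weight for category: %s",
                 paste(unique(rl_category[bad]), collapse = ", ")))
  }
  unname(map[rl_category])
}

#' Red-List-controlled random selection
#'
#' Draws a random species set whose Red List category composition matches a
#' template selection exactly: for each category, as many species as the
#' template holds are drawn uniformly without replacement from that
#' category's pool in the universe. This controls for any association
#' between phylogeny and extinction risk when benchmarking PD-maximizing
#' sets.
#'
#' @param universe candidate species ids.
#' @param rl_of named character vector mapping species id to Red List
#'   category, covering universe and template.
#' @param template a `selection_result` (or character vector of species)
#'   whose category histogram is to be reproduced.
#' @param seed integer seed.
#' @return a `selection_result` with strategy `"rl_controlled"`.
#' @export
sample_rl_controlled <- function(universe, rl_of, template, seed = 1L) {
  universe <- unique(normalize_label(universe))
  names(rl_of) <- normalize_label(names(rl_of))
  tmpl_taxa <- if (inherits(template, "selection_result")) template$taxa
               else normalize_label(template)
  missing <- setdiff(c(universe, tmpl_taxa), names(rl_of))
  if (length(missing) > 0L) {
    stop(sprintf("no Red List category for species: %s",
                 paste(missing, collapse = ", ")))
  }
  need <- table(rl_of[tmpl_taxa])
  taxa <- with_seed(derive_seed(seed, 97L), {
    picked <- character(0)
    for (categ in names(need)) {
      pool <- universe[rl_of[universe] == categ]
      n_need <- need[[categ]]
      if (length(pool) < n_need) {
        stop(sprintf(
          "universe has only %d %s species but the template requires %d",
          length(pool), categ, n_need))
      }
      picked <- c(picked, pool[sample.int(length(pool), n_need)])
    }
    picked
  })
  new_selection_result("rl_controlled", taxa = taxa)
}
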