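# Core phylogenetic metrics: Faith's PD, fair-proportion evolutionary
# distinctiveness (ED), EDGE scores, and the tip-shuffle dispersion SES.
#
# PD is ROOTED throughout: the PD of a species set includes the path from
# every member to the global root, each edge counted once. This convention
# makes the fair-proportion partition exact (ED sums to total branch length)
# and makes PD of the full tip set equal the tree's total branch length.

# ---- internal tree indexing -------------------------------------------------

# Precompute, for one phylo tree: edge lengths, per-tip root paths (edge row
# indices), the number of descendant tips per edge, and a tips x edges
# incidence matrix used to evaluate PD over many subsets at once.
tree_index <- function(tree) {
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  parent_edge <- integer(max(tree$edge))  # edge row whose child is this node
  parent_edge[tree$edge[, 2L]] <- seq_len(nedge)
  root <- ntip + 1L
  paths <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    node <- i
    p <- integer(0)
    while (node != root) {
      e <- parent_edge[node]
      p[length(p) + 1L] <- e
      node <- tree$edge[e, 1L]
    }
    paths[[i]] <- p
  }
  n_desc <- integer(nedge)
  for (i in seq_len(ntip)) n_desc[paths[[i]]] <- n_desc[paths[[i]]] + 1L
  incidence <- Matrix::sparseMatrix(
    i = rep.int(seq_len(ntip), lengths(paths)),
    j = unlist(paths),
    x = 1,
    dims = c(ntip, nedge),
    dimnames = list(tree$tip.label, NULL)
  )
  list(
    tip_labels = tree$tip.label,
    edge_length = tree$edge.length,
    paths = paths,
    n_desc = n_desc,
    incidence = incidence,
    total_length = sum(tree$edge.length)
  )
}

match_taxa <- function(taxa, tip_labels) {
  taxa <- normalize_label(taxa)
  idx <- match(taxa, tip_labels)
  if (anyNA(idx)) {
    stop(sprintf("taxa not found in tree: %s",
                 paste(taxa[is.na(idx)], collapse = ", ")))
  }
  idx
}

# PD of many subsets at once. `subsets` is a list of tip-index vectors.
pd_batch <- function(idx, subsets) {
  k <- lengths(subsets)
  if (any(k == 0L)) stop("PD of an empty species set is undefined")
  S <- Matrix::sparseMatrix(
    i = rep.int(seq_along(subsets), k),
    j = unlist(subsets),
    x = 1,
    dims = c(length(subsets), nrow(idx$incidence))
  )
  covered <- (S %*% idx$incidence) > 0
  as.numeric(covered %*% idx$edge_length)
}

# ---- PD ---------------------------------------------------------------------

#' Faith's phylogenetic diversity of a species set
#'
#' Rooted Faith PD: the sum of the branch lengths of every edge lying on a
#' path from a member of `taxa` to the root, each edge counted once.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param taxa nonempty character vector of tip labels.
#' @return a single numeric PD value, in the tree's branch-length units.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):2);")
#' pd(tr, c("A", "B", "C", "D"))  # 7: total branch length
#' pd(tr, c("A", "C"))            # 5
pd <- function(tree, taxa) {
  tree <- validate_phylogeny(tree)
  if (length(taxa) == 0L) stop("PD of an empty species set is undefined")
  idx <- tree_index(tree)
  tips <- unique(match_taxa(taxa, idx$tip_labels))
  edges <- unique(unlist(idx$paths[tips]))
  sum(idx$edge_length[edges])
}

# ---- fair-proportion ED -----------------------------------------------------

#' Fair-proportion evolutionary distinctiveness
#'
#' Partitions the tree's total branch length among its tips: each edge's
#' length is divided equally among the tips descending from it, and a tip's
#' ED is the sum of its shares along its root path. ED values sum exactly to
#' the total branch length of the tree.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return named numeric vector of ED scores, one per tip.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):2);")
#' fair_proportion_ed(tr)  # A = B = 1.5, C = D = 2
fair_proportion_ed <- function(tree) {
  tree <- validate_phylogeny(tree)
  idx <- tree_index(tree)
  share <- idx$edge_length / idx$n_desc
  ed <- as.numeric(idx$incidence %*% share)
  names(ed) <- idx$tip_labels
  ed
}

#' Median ED (and per-tree ED) across a tree ensemble
#'
#' Computes fair-proportion ED on every tree in the ensemble and summarizes
#' per species. The median over an even number of trees is the mean of the
#' two central values (the standard sample median).
#'
#' @param ensemble a [tree_ensemble()].
#' @return a data frame with columns `species`, `ed_median`, `ed_mean`,
#'   `n_trees`, plus an attribute `"ed_matrix"` (species x trees).
#' @export
ed_table <- function(ensemble) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  species <- ensemble$shared_tipset
  mat <- vapply(ensemble$trees, function(tr) {
    ed <- fair_proportion_ed(tr)
    ed[species]
  }, numeric(length(species)))
  mat <- matrix(mat, nrow = length(species),
                dimnames = list(species, NULL))
  out <- data.frame(
    species = species,
    ed_median = apply(mat, 1L, stats::median),
    ed_mean = rowMeans(mat),
    n_trees = length(ensemble$trees),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "ed_matrix") <- mat
  out
}

# ---- EDGE -------------------------------------------------------------------

#' Global endangerment (GE) weight of a Red List category
#'
#' Integer extinction-risk rank used in the EDGE score: LC = 0, NT = 1,
#' VU = 2, EN = 3, CR = 4, EW = 5. Data-deficient (DD) species carry no
#' defined risk rank and raise an error.
#'
#' @param rl_category character vector of Red List categories.
#' @return integer vector of GE weights.
#' @export
ge_weight <- function(rl_category) {
  map <- c(LC = 0L, NT = 1L, VU = 2L, EN = 3L, CR = 4L, EW = 5L)
  rl_category <- toupper(trimws(rl_category))
  if (any(rl_category == "DD")) {
    stop("GE is undefined for data-deficient (DD) species")
  }
  bad <- !(rl_category %in% names(map))
  if (any(bad)) {
    stop(sprintf("unknown Red List category: %s",
                 paste(unique(rl_category[bad]), collapse = ", ")))
  }
  unname(map[rl_category])
}

#' EDGE score
#'
#' Evolutionarily Distinct and Globally Endangered score,
#' `ln(1 + ED) + GE * ln(2)`: each step up the Red List doubles the
#' expected loss term, so equally distinct species one category apart differ
#' by exactly `ln 2`.
#'
#' @param ed numeric vector of ED scores (nonnegative).
#' @param rl_category Red List categories, recycled against `ed`.
#' @return numeric vector of EDGE scores.
#' @export
#' @examples
#' edge_score(1.5, "EN")  # log(2.5) + 3 * log(2)
edge_score <- function(ed, rl_category) {
  if (any(ed < 0)) stop("ED must be nonnegative")
  ge <- ge_weight(rl_category)
  log1p(ed) + ge * log(2)
}

#' Median EDGE scores across a tree ensemble
#'
#' @param ensemble a [tree_ensemble()].
#' @param table a species table providing `rl_category` per species; DD
#'   species are dropped (no GE is defined for them).
#' @return data frame with `species`, `rl_category`, `ed_median`,
#'   `edge_median`.
#' @export
edge_table <- function(ensemble, table) {
  table <- as_species_table(table)
  ed <- ed_table(ensemble)
  mat <- attr(ed, "ed_matrix")
  keep <- table$species[table$rl_category != "DD"]
  keep <- intersect(ed$species, keep)
  rl <- table$rl_category[match(keep, table$species)]
  ge <- ge_weight(rl)
  edge_mat <- log1p(mat[keep, , drop = FALSE]) + ge * log(2)
  data.frame(
    species = keep,
    rl_category = rl,
    ed_median = ed$ed_median[match(keep, ed$species)],
    edge_median = apply(edge_mat, 1L, stats::median),
    stringsAsFactors = FALSE
  )
}

# ---- SES report -------------------------------------------------------------

#' Standardized effect size report
#'
#' Builds an SES report from an observed mean, a null mean and a null
#' standard deviation: `SES = (m_obs - m_null) / sd_null`. The significance
#' tier uses the standard-normal two-sided quantiles: `*` for |SES| >= 1.96,
#' `**` for |SES| >= 2.576, `***` for |SES| >= 3.891, `ns` otherwise.
#'
#' @param m_obs observed mean.
#' @param m_null null-distribution mean.
#' @param sd_null null-distribution standard deviation (must be > 0).
#' @param n_obs,n_null numbers of observed / null replicates.
#' @return an object of class `ses_report`.
#' @export
ses_report <- function(m_obs, m_null, sd_null, n_obs = NA_integer_,
                       n_null = NA_integer_) {
  if (!is.finite(sd_null) || sd_null <= 0) {
    stop("null distribution is degenerate (sd_null <= 0)")
  }
  ses <- (m_obs - m_null) / sd_null
  structure(
    list(m_obs = m_obs, m_null = m_null, sd_null = sd_null, ses = ses,
         n_obs = n_obs, n_null = n_null, tier = ses_tier(ses)),
    class = "ses_report"
  )
}

ses_tier <- function(ses) {
  a <- abs(ses)
  if (a >= 3.891) "***" else if (a >= 2.576) "**" else if (a >= 1.96) "*" else "ns"
}

#' @export
print.ses_report <- function(x, ...) {
  cat(sprintf("SES = %.3f (obs %.3f, null %.3f +/- %.3f) [%s]\n",
              x$ses, x$m_obs, x$m_null, x$sd_null, x$tier))
  invisible(x)
}

# ---- dispersion SES ---------------------------------------------------------

#' Phylogenetic dispersion of a labeled species set
#'
#' Tests whether a set of species spans more or less PD than expected for a
#' random set of the same size. For each tree in the ensemble the null is
#' built by shuffling species names across the tree tips and recomputing PD
#' `n_shuffles` times; the per-tree SES is averaged across trees. Negative
#' SES indicates phylogenetic clumping, positive SES dispersion.
#'
#' @param ensemble a [tree_ensemble()].
#' @param taxa character vector of labeled species, a strict nonempty subset
#'   of the shared tip set.
#' @param n_shuffles number of label shuffles per tree (>= 2).
#' @param seed integer seed.
#' @return a `ses_report` whose fields are means across trees; also carries
#'   `ses_per_tree` as an attribute.
#' @export
dispersion_ses <- function(ensemble, taxa, n_shuffles = 1000L, seed = 1L) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  if (n_shuffles < 2L) stop("n_shuffles must be at least 2")
  taxa <- unique(normalize_label(taxa))
  ntip <- length(ensemble$shared_tipset)
  if (length(taxa) == 0L || length(taxa) >= ntip) {
    stop("taxa must be a nonempty strict subset of the tips (the tip-shuffle null is degenerate otherwise)")
  }
  missing <- setdiff(taxa, ensemble$shared_tipset)
  if (length(missing) > 0L) {
    stop(sprintf("taxa not in the shared tip set: %s",
                 paste(missing, collapse = ", ")))
  }
  k <- length(taxa)
  per_tree <- with_seed(derive_seed(seed, 7L), {
    vapply(seq_along(ensemble$trees), function(t) {
      idx <- tree_index(ensemble$trees[[t]])
      obs <- pd_batch(idx, list(match_taxa(taxa, idx$tip_labels)))
      nulls <- pd_batch(idx, lapply(seq_len(n_shuffles), function(s) {
        sample.int(ntip, k)
      }))
      sd_null <- stats::sd(nulls)
      if (sd_null <= 0) stop("degenerate tip-shuffle null (sd = 0)")
      c(obs, mean(nulls), sd_null, (obs - mean(nulls)) / sd_null)
    }, numeric(4))
  })
  rep <- ses_report(
    m_obs = mean(per_tree[1L, ]),
    m_null = mean(per_tree[2L, ]),
    sd_null = mean(per_tree[3L, ]),
    n_obs = length(ensemble$trees),
    n_null = n_shuffles
  )
  # the reported SES is the mean of per-tree SES values, not the SES of means
  rep$ses <- mean(per_tree[4L, ])
  rep$tier <- ses_tier(rep$ses)
  attr(rep, "ses_per_tree") <- per_tree[4L, ]
  rep
}
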