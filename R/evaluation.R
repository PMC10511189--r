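# Inferential layer: benefit-capture counting, SES comparisons between
# selection strategies, order-level overrepresentation permutation tests,
# ED/FDist top-set overlap, and distinctiveness statistics.

#' Species flagged for a utilization category
#'
#' `"all"` is the union of the four main consumptive categories (food,
#' materials, medicine, pets); `include_other = TRUE` additionally counts
#' species whose recorded uses could not be reconciled with a main category
#' (the `use_other` flag), mirroring the sensitivity variant of the
#' combined analysis.
#'
#' @param table a species table.
#' @param category one of `"food"`, `"materials"`, `"medicine"`, `"pets"`,
#'   `"other"`, `"all"`.
#' @param include_other include `use_other` species in `"all"`.
#' @return character vector of species ids.
#' @export
flagged_species <- function(table, category, include_other = FALSE) {
  table <- as_species_table(table)
  if (category == "all") {
    cats <- c("food", "materials", "medicine", "pets")
    if (include_other) cats <- c(cats, "other")
    flag <- Reduce(`|`, lapply(use_flag_column(cats), function(cl) table[[cl]]))
  } else if (category %in% USE_CATEGORIES) {
    flag <- table[[use_flag_column(category)]]
  } else {
    stop(sprintf("unknown utilization category: %s", category))
  }
  table$species[flag]
}

#' Count flagged species captured by a selection
#'
#' @param result a `selection_result` or character vector of species.
#' @param table a species table.
#' @param category utilization category (see [flagged_species()]).
#' @param include_other include `use_other` in `"all"`.
#' @return integer count of captured species.
#' @export
count_captured <- function(result, table, category, include_other = FALSE) {
  taxa <- if (inherits(result, "selection_result")) result$taxa
          else normalize_label(result)
  length(intersect(taxa, flagged_species(table, category, include_other)))
}

#' Summarize benefit capture across replicate selections
#'
#' Counts, for every replicate selection, how many species flagged for the
#' category were captured, and reports the mean with an empirical 95%
#' confidence interval (the 2.5 and 97.5 percentiles of the replicate
#' counts).
#'
#' @param results list of `selection_result` objects (one strategy).
#' @param table a species table.
#' @param category utilization category.
#' @param include_other include `use_other` in `"all"`.
#' @return an object of class `capture_summary` with fields `strategy`,
#'   `fraction`, `category`, `counts`, `mean`, `ci95_low`, `ci95_high`.
#' @export
capture_summary <- function(results, table, category, include_other = FALSE) {
  stopifnot(length(results) > 0L)
  flagged <- flagged_species(table, category, include_other)
  counts <- vapply(results, function(r) {
    taxa <- if (inherits(r, "selection_result")) r$taxa else normalize_label(r)
    length(intersect(taxa, flagged))
  }, integer(1))
  ci <- unname(stats::quantile(counts, c(0.025, 0.975), type = 7))
  structure(
    list(strategy = results[[1L]]$strategy, fraction = results[[1L]]$fraction,
         category = category, counts = counts, mean = mean(counts),
         ci95_low = ci[1L], ci95_high = ci[2L]),
    class = "capture_summary"
  )
}

#' @export
print.capture_summary <- function(x, ...) {
  cat(sprintf("%s / %s: mean %.2f captured [%.1f, %.1f] over %d sets\n",
              x$strategy, x$category, x$mean, x$ci95_low, x$ci95_high,
              length(x$counts)))
  invisible(x)
}

#' SES of one capture distribution against a null capture distribution
#'
#' Standardized effect size `(mean_obs - mean_null) / sd_null`, where
#' `sd_null` is the standard deviation of the null replicate counts.
#' Positive SES means the focal strategy captures more flagged species than
#' the null strategy.
#'
#' @param observed,null `capture_summary` objects for the same category and
#'   fraction.
#' @return a `ses_report`.
#' @export
ses_between <- function(observed, null) {
  stopifnot(inherits(observed, "capture_summary"),
            inherits(null, "capture_summary"))
  if (!identical(observed$category, null$category)) {
    stop("capture summaries are for different categories")
  }
  if (!isTRUE(all.equal(observed$fraction, null$fraction))) {
    stop("capture summaries are for different sample fractions")
  }
  if (length(null$counts) < 2L) stop("null needs at least 2 replicates")
  ses_report(m_obs = observed$mean, m_null = mean(null$counts),
             sd_null = stats::sd(null$counts),
             n_obs = length(observed$counts), n_null = length(null$counts))
}

#' Taxonomic-order overrepresentation permutation test
#'
#' For each taxonomic order, compares the observed number of species flagged
#' for a utilization category against a null built from `n_perm` uniform
#' random species sets of the same size. An order is flagged `over` when its
#' observed count is at or above the 97.5th percentile of its null counts,
#' `under` at or below the 2.5th percentile, `ns` otherwise.
#'
#' @param table a species table.
#' @param category utilization category.
#' @param n_perm number of random sets (default 999).
#' @param seed integer seed.
#' @param include_other include `use_other` in `"all"`.
#' @return data frame with columns `order`, `n_species`, `observed`,
#'   `null_mean`, `lower`, `upper`, `verdict`; the null count matrix is
#'   attached as attribute `"null_counts"`.
#' @export
order_overrepresentation <- function(table, category, n_perm = 999L,
                                     seed = 1L, include_other = FALSE) {
  table <- as_species_table(table)
  flagged <- flagged_species(table, category, include_other)
  m <- length(flagged)
  if (m == 0L) stop(sprintf("no species flagged for category %s", category))
  if (n_perm < 1L) stop("n_perm must be >= 1")
  orders <- sort(unique(table$order))
  ord_of <- factor(table$order, levels = orders)
  observed <- as.integer(table(ord_of[table$species %in% flagged]))
  n <- nrow(table)
  null_counts <- with_seed(derive_seed(seed, 113L), {
    vapply(seq_len(n_perm), function(p) {
      pick <- sample.int(n, m)
      as.integer(table(ord_of[pick]))
    }, integer(length(orders)))
  })
  null_counts <- matrix(null_counts, nrow = length(orders))
  lower <- apply(null_counts, 1L, stats::quantile, probs = 0.025, type = 1)
  upper <- apply(null_counts, 1L, stats::quantile, probs = 0.975, type = 1)
  verdict <- ifelse(observed >= upper, "over",
                    ifelse(observed <= lower, "under", "ns"))
  # degenerate nulls (e.g. an order holding every species, where the null
  # and observed coincide by construction) carry no signal
  verdict[upper <= lower | apply(null_counts, 1L, stats::sd) == 0] <- "ns"
  out <- data.frame(
    order = orders,
    n_species = as.integer(table(ord_of)),
    observed = observed,
    null_mean = rowMeans(null_counts),
    lower = lower, upper = upper,
    verdict = verdict,
    stringsAsFactors = FALSE
  )
  attr(out, "null_counts") <- null_counts
  out
}

#' Overlap of the top-k species under two distinctiveness scores
#'
#' Selects the top `k = round_half_up(fraction * |universe|)` species under
#' each score (deterministic rank selection, ties by species id) and
#' partitions them into species captured by both scores or by one only.
#'
#' @param scores_a,scores_b named numeric score vectors covering `universe`
#'   (e.g. median ED and FDist).
#' @param universe species ids to rank; defaults to the names of `scores_a`.
#' @param fraction top fraction to select, in `(0, 1]`.
#' @return an object of class `overlap_report`: list with `fraction`, `k`,
#'   `both`, `a_only`, `b_only` and the corresponding counts.
#' @export
top_set_overlap <- function(scores_a, scores_b, universe = NULL, fraction) {
  if (is.null(universe)) universe <- names(scores_a)
  universe <- unique(normalize_label(universe))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- max(1L, round_half_up(fraction * length(universe)))
  top_a <- rank_select(scores_a, universe, k, strategy = "ed_rank")$taxa
  top_b <- rank_select(scores_b, universe, k, strategy = "fdist_rank")$taxa
  both <- intersect(top_a, top_b)
  structure(
    list(fraction = fraction, k = k,
         both = both, a_only = setdiff(top_a, both),
         b_only = setdiff(top_b, both),
         n_both = length(both), n_a_only = k - length(both),
         n_b_only = k - length(both)),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("top-%d overlap: %d shared (%.1f%%), %d score-A only, %d score-B only\n",
              x$k, x$n_both, 100 * x$n_both / x$k, x$n_a_only, x$n_b_only))
  invisible(x)
}

# ---- distinctiveness statistics --------------------------------------------

#' Dunn's test of pairwise stochastic dominance after Kruskal-Wallis
#'
#' Rank-sum pairwise z statistics on the pooled ranks with the standard tie
#' correction, and Holm-adjusted two-sided p-values.
#'
#' @param x numeric response.
#' @param g grouping factor.
#' @param p_adjust_method adjustment passed to [stats::p.adjust()]
#'   (default `"holm"`).
#' @return data frame with `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(x, g, p_adjust_method = "holm") {
  g <- factor(g)
  if (nlevels(g) < 2L) stop("need at least two groups")
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  if (any(ni < 2L)) stop("every group needs at least two members")
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(levels(g), 2L)
  res <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[[i]] + 1 / ni[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    z = res["z", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust_method)
  rownames(out) <- NULL
  out
}

#' Distinctiveness statistics for utilization categories
#'
#' The statistical battery applied to per-species distinctiveness scores:
#' a Kruskal-Wallis test across utilization categories with Dunn pairwise
#' comparisons (Holm-adjusted), Welch t tests of each score for utilized vs
#' non-utilized species, and the Pearson correlation between ED and FDist.
#' Species flagged for several categories contribute to each of them in the
#' across-category comparison.
#'
#' @param table a species table.
#' @param ed named numeric vector of (median) ED scores covering the table's
#'   species.
#' @param categories utilization categories to compare (default the four
#'   main ones).
#' @return list with elements `kruskal` (htest), `dunn` (data frame),
#'   `welch` (data frame: category x score t/df/p), `pearson` (htest).
#' @export
compare_distinctiveness <- function(table, ed,
                                    categories = c("food", "materials",
                                                   "medicine", "pets")) {
  table <- as_species_table(table)
  names(ed) <- normalize_label(names(ed))
  missing <- setdiff(table$species, names(ed))
  if (length(missing) > 0L) {
    stop(sprintf("no ED score for species: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  ed <- ed[table$species]
  # across-category comparison (a species may appear in several categories)
  vals <- list(); grp <- list()
  for (categ in categories) {
    sp <- flagged_species(table, categ)
    if (length(sp) >= 2L) {
      vals[[categ]] <- ed[sp]
      grp[[categ]] <- rep(categ, length(sp))
    }
  }
  if (length(vals) < 2L) stop("need at least two non-empty categories")
  x <- unlist(vals, use.names = FALSE)
  g <- factor(unlist(grp, use.names = FALSE))
  kres <- stats::kruskal.test(x, g)
  dres <- dunn_test(x, g)
  # utilized vs non-utilized, per score
  used_all <- table$species %in% flagged_species(table, "all")
  welch <- do.call(rbind, lapply(c("ed", "fdist"), function(score) {
    v <- if (score == "ed") ed else stats::setNames(table$fdist, table$species)
    tt <- stats::t.test(v[table$species[used_all]],
                        v[table$species[!used_all]])
    data.frame(score = score, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean_utilized = unname(tt$estimate[1L]),
               mean_non_utilized = unname(tt$estimate[2L]),
               stringsAsFactors = FALSE)
  }))
  pres <- stats::cor.test(ed, table$fdist, method = "pearson")
  list(kruskal = kres, dunn = dres, welch = welch, pearson = pres)
}
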