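# Reading, validating and reconciling phylogenies and species tables.

#' Construct a tree ensemble
#'
#' Wraps a list of rooted, branch-length-bearing `phylo` trees that share an
#' identical tip set — e.g. a sample from a posterior distribution of
#' phylogenies — and validates them. All downstream metrics (PD, ED, EDGE,
#' dispersion) are averaged across the ensemble to propagate phylogenetic
#' uncertainty.
#'
#' @param trees a `phylo`, `multiPhylo`, or list of `phylo` objects. Tip
#'   labels are normalized (whitespace trimmed, underscores replaced by
#'   spaces) before comparison.
#' @return an object of class `tree_ensemble`: a list with elements `trees`
#'   (a `multiPhylo`) and `shared_tipset` (character vector of tip labels).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):2);")
#' ens <- tree_ensemble(tr)
#' ens$shared_tipset
tree_ensemble <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0L) stop("ensemble must contain at least one tree")
  trees <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    if (!inherits(tr, "phylo")) {
      stop(sprintf("element %d is not a phylogenetic tree", i))
    }
    validate_phylogeny(tr, index = i)
  })
  tipsets <- lapply(trees, function(tr) sort(tr$tip.label))
  ref <- tipsets[[1L]]
  for (i in seq_along(tipsets)) {
    if (!identical(tipsets[[i]], ref)) {
      diffs <- union(setdiff(ref, tipsets[[i]]), setdiff(tipsets[[i]], ref))
      stop(sprintf(
        "tree %d does not share the ensemble tip set; differing tips: %s",
        i, paste(sort(diffs), collapse = ", ")
      ))
    }
  }
  class(trees) <- "multiPhylo"
  structure(
    list(trees = trees, shared_tipset = ref),
    class = "tree_ensemble"
  )
}

# Validate a single phylogeny: rooted, branch lengths present and
# nonnegative (at least one positive), unique tip labels. Tip labels are
# normalized in place. Polytomies and zero-length branches are accepted, as
# both occur in posterior tree samples.
validate_phylogeny <- function(tree, index = NA_integer_) {
  where <- if (is.na(index)) "tree" else sprintf("tree %d", index)
  tree$tip.label <- normalize_label(tree$tip.label)
  if (is.null(tree$edge.length)) {
    stop(sprintf("%s has no branch lengths; PD is undefined without them", where))
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop(sprintf("%s has missing or negative branch lengths", where))
  }
  if (!any(tree$edge.length > 0)) {
    stop(sprintf("%s has no positive branch length", where))
  }
  # A basal polytomy is indistinguishable in Newick from an unrooted tree;
  # posterior samples legitimately contain polytomies, so the representation
  # root is taken as THE root (rooted-PD convention) rather than rejected.
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop(sprintf("%s has duplicate tip labels: %s", where,
                 paste(dup, collapse = ", ")))
  }
  tree
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat(sprintf("Tree ensemble: %d tree(s), %d shared tips\n",
              length(x$trees), length(x$shared_tipset)))
  invisible(x)
}

#' @export
length.tree_ensemble <- function(x) length(x$trees)

#' Read an ensemble of phylogenies
#'
#' Reads one or more rooted trees with branch lengths from a Newick file
#' (one tree per line) or a NEXUS TREES block, and validates that all trees
#' carry an identical tip set.
#'
#' @param path path to the tree file.
#' @param format `"newick"` (default) or `"nexus"`.
#' @return a [tree_ensemble()].
#' @export
read_tree_ensemble <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("tree file not found: %s", path))
  trees <- if (format == "newick") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop(sprintf("no trees found in %s", path))
    parsed <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      tr <- tryCatch(suppressWarnings(ape::read.tree(text = lines[[i]])),
                     error = function(e) NULL)
      if (is.null(tr) || !inherits(tr, "phylo")) {
        stop(sprintf("failed to parse tree %d in %s", i, path))
      }
      parsed[[i]] <- tr
    }
    parsed
  } else {
    tr <- tryCatch(ape::read.nexus(path), error = function(e) {
      stop(sprintf("failed to parse NEXUS file %s: %s", path,
                   conditionMessage(e)))
    })
    if (inherits(tr, "phylo")) {
      list(tr)
    } else {
      # index through the multiPhylo so compressed tip labels are restored
      lapply(seq_along(tr), function(i) tr[[i]])
    }
  }
  tree_ensemble(trees)
}

#' Write an ensemble of phylogenies
#'
#' Writes the ensemble as multi-tree Newick, one tree per line.
#'
#' @param ensemble a [tree_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  ape::write.tree(ensemble$trees, file = path)
  invisible(path)
}

#' Read a species attribute table
#'
#' Reads a comma- or tab-delimited table with one row per species and the
#' columns `species`, `order`, `rl_category`, `use_food`, `use_materials`,
#' `use_medicine`, `use_pets`, `use_other`, `fdist`. Use flags are coerced
#' from 0/1 or true/false; `rl_category` must come from the closed Red List
#' vocabulary ([RL_CATEGORIES]).
#'
#' @param path path to the delimited file. The delimiter (comma or tab) is
#'   detected from the header line.
#' @return a `data.frame` with normalized species ids, factor-free character
#'   columns, logical use flags and numeric `fdist`.
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("species table not found: %s", path))
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  as_species_table(df)
}

#' Validate a species attribute data frame
#'
#' @param df a data frame with the columns described in
#'   [read_species_table()].
#' @return the validated, type-coerced data frame.
#' @export
as_species_table <- function(df) {
  required <- c("species", "order", "rl_category",
                paste0("use_", USE_CATEGORIES), "fdist")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("species table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- df[, required]
  df$species <- normalize_label(as.character(df$species))
  if (anyDuplicated(df$species)) {
    dup <- unique(df$species[duplicated(df$species)])
    stop(sprintf("duplicate species id(s): %s", paste(dup, collapse = ", ")))
  }
  df$order <- as.character(df$order)
  df$rl_category <- toupper(trimws(as.character(df$rl_category)))
  bad <- !(df$rl_category %in% RL_CATEGORIES)
  if (any(bad)) {
    stop(sprintf(
      "unknown rl_category value(s) %s for species: %s (allowed: %s)",
      paste(unique(df$rl_category[bad]), collapse = ", "),
      paste(df$species[bad], collapse = ", "),
      paste(RL_CATEGORIES, collapse = ", ")
    ))
  }
  for (col in paste0("use_", USE_CATEGORIES)) {
    df[[col]] <- coerce_flag(df[[col]], col)
  }
  df$fdist <- as.numeric(df$fdist)
  if (anyNA(df$fdist) || any(df$fdist < 0)) {
    stop("fdist must be nonnegative and non-missing for every species")
  }
  rownames(df) <- NULL
  df
}

coerce_flag <- function(x, col) {
  if (is.logical(x)) return(x)
  x_chr <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x_chr))
  out[x_chr %in% c("1", "true")] <- TRUE
  out[x_chr %in% c("0", "false")] <- FALSE
  if (anyNA(out)) {
    stop(sprintf("column %s has values other than 0/1/true/false", col))
  }
  out
}

#' Write a species table
#'
#' @param table a species table (see [read_species_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(table, path) {
  out <- table
  for (col in paste0("use_", USE_CATEGORIES)) {
    out[[col]] <- as.integer(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reconcile a tree ensemble with a species table
#'
#' Matches tree tips to table rows by normalized label and either prunes both
#' to their common species set (`policy = "intersect"`, reporting the number
#' dropped on each side) or fails on any mismatch (`policy = "strict"`).
#'
#' @param ensemble a [tree_ensemble()].
#' @param table a species table.
#' @param policy `"intersect"` or `"strict"`.
#' @return a list with elements `ensemble`, `table`, `dropped_tips` and
#'   `dropped_rows`.
#' @export
reconcile <- function(ensemble, table, policy = c("intersect", "strict")) {
  policy <- match.arg(policy)
  stopifnot(inherits(ensemble, "tree_ensemble"))
  table <- as_species_table(table)
  tips <- ensemble$shared_tipset
  ids <- table$species
  only_tree <- setdiff(tips, ids)
  only_table <- setdiff(ids, tips)
  if (policy == "strict") {
    if (length(only_tree) > 0L || length(only_table) > 0L) {
      stop(sprintf(
        "tree/table mismatch under strict policy; unmatched ids: %s",
        paste(sort(c(only_tree, only_table)), collapse = ", ")
      ))
    }
    return(list(ensemble = ensemble, table = table,
                dropped_tips = character(0), dropped_rows = character(0)))
  }
  common <- intersect(tips, ids)
  if (length(common) < 2L) {
    stop("fewer than two species shared between trees and table")
  }
  if (length(only_tree) > 0L) {
    message(sprintf("reconcile: dropping %d tip(s) absent from the table",
                    length(only_tree)))
    trees <- lapply(ensemble$trees, ape::keep.tip, tip = common)
    ensemble <- tree_ensemble(trees)
  }
  if (length(only_table) > 0L) {
    message(sprintf("reconcile: dropping %d table row(s) absent from the trees",
                    length(only_table)))
    table <- table[table$species %in% common, , drop = FALSE]
    rownames(table) <- NULL
  }
  list(ensemble = ensemble, table = table,
       dropped_tips = only_tree, dropped_rows = only_table)
}
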