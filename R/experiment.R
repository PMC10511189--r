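# End-to-end experiment orchestration: generate or load inputs, score,
# select under every requested strategy x fraction, evaluate capture per
# utilization category against a null strategy, and write reports plus a
# manifest with full seed provenance. The R functions are the interface;
# a config can also be supplied as a YAML file.

#' Experiment configuration
#'
#' Validates the configuration of a full capture experiment. Either
#' `synth` (a [synth_config()] or a list of its arguments) or both
#' `trees_path` and `species_path` must be provided.
#'
#' @param synth synthetic-data configuration, or `NULL` to read real inputs.
#' @param trees_path,species_path input files (used when `synth` is `NULL`).
#' @param fractions sample fractions, strictly increasing, in `(0, 1]`.
#' @param strategies selection strategies to run (subset of
#'   `r paste(SELECTION_STRATEGIES, collapse = ", ")`).
#' @param null_strategy stochastic strategy used as the SES null
#'   (`"random_uniform"`, `"rl_weighted"`, `"rl_controlled"` or
#'   `"fdist_weighted"`).
#' @param categories utilization categories to evaluate.
#' @param replicates replicate sets for stochastic strategies.
#' @param sets_per_tree greedy sets per tree.
#' @param threatened_only restrict the selection universe to threatened
#'   species (VU/EN/CR/EW), with LC/NT species secured (DD dropped).
#' @param seed master seed.
#' @param out_dir output directory, or `NULL` to keep results in memory.
#' @return a validated `experiment_config` list.
#' @export
experiment_config <- function(synth = synth_config(),
                              trees_path = NULL, species_path = NULL,
                              fractions = c(0.025, 0.05, 0.10, 0.25, 0.50),
                              strategies = c("greedy_pd", "random_uniform"),
                              null_strategy = "random_uniform",
                              categories = c("food", "materials", "medicine",
                                             "pets", "all"),
                              replicates = 1000L,
                              sets_per_tree = 10L,
                              threatened_only = FALSE,
                              seed = 1L,
                              out_dir = NULL) {
  if (is.null(synth) && (is.null(trees_path) || is.null(species_path))) {
    stop("provide either a synth config or both trees_path and species_path")
  }
  if (!is.null(synth) && !inherits(synth, "synth_config")) {
    synth <- do.call(synth_config, synth)
  }
  if (!is.null(trees_path) && !file.exists(trees_path)) {
    stop(sprintf("trees file not found: %s", trees_path))
  }
  if (!is.null(species_path) && !file.exists(species_path)) {
    stop(sprintf("species file not found: %s", species_path))
  }
  if (any(fractions <= 0 | fractions > 1) || is.unsorted(fractions, strictly = TRUE)) {
    stop("fractions must be strictly increasing and in (0, 1]")
  }
  bad <- setdiff(strategies, SELECTION_STRATEGIES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown strategies: %s", paste(bad, collapse = ", ")))
  }
  stopifnot(null_strategy %in% c("random_uniform", "rl_weighted",
                                 "rl_controlled", "fdist_weighted"),
            replicates >= 2L, sets_per_tree >= 1L)
  structure(
    list(synth = synth, trees_path = trees_path, species_path = species_path,
         fractions = fractions, strategies = unique(strategies),
         null_strategy = null_strategy, categories = categories,
         replicates = as.integer(replicates),
         sets_per_tree = as.integer(sets_per_tree),
         threatened_only = isTRUE(threatened_only),
         seed = as.integer(seed), out_dir = out_dir),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from YAML
#'
#' Keys mirror the arguments of [experiment_config()]; the `synth` key holds
#' [synth_config()] arguments (`prevalence`, `clumping` and
#' `rl_proportions` as named maps).
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synth)) {
    for (key in c("prevalence", "clumping", "rl_proportions")) {
      if (!is.null(raw$synth[[key]])) raw$synth[[key]] <- unlist(raw$synth[[key]])
    }
  }
  if (!is.null(raw$fractions)) raw$fractions <- as.numeric(unlist(raw$fractions))
  do.call(experiment_config, raw)
}

# Generate one replicate set for a stochastic null/selection strategy.
draw_stochastic_set <- function(strategy, universe, table, fraction, k,
                                template = NULL, seed = 1L, replicate = NA_integer_) {
  res <- switch(
    strategy,
    random_uniform = sample_weighted(universe, 1, k, seed = seed,
                                     strategy = "random_uniform"),
    rl_weighted = {
      rl <- stats::setNames(table$rl_category, table$species)[universe]
      sample_weighted(universe, rl_index_weight(rl), k, seed = seed,
                      strategy = "rl_weighted")
    },
    fdist_weighted = {
      w <- stats::setNames(table$fdist, table$species)[universe]
      if (any(w <= 0)) w <- w + max(w) * 1e-6 + 1e-12
      sample_weighted(universe, w, k, seed = seed,
                      strategy = "fdist_weighted")
    },
    rl_controlled = {
      rl <- stats::setNames(table$rl_category, table$species)
      sample_rl_controlled(universe, rl, template, seed = seed)
    },
    stop(sprintf("not a stochastic strategy: %s", strategy))
  )
  res$fraction <- fraction
  res$replicate <- replicate
  res
}

#' Run a full capture experiment
#'
#' Executes every requested strategy at every sample fraction, evaluates the
#' number of flagged species captured for every utilization category, and
#' computes SES reports of each non-null strategy against the configured
#' null strategy. Deterministic given the config (including its seed).
#'
#' @param config an [experiment_config()].
#' @return a list of class `experiment_result` with elements `cells` (data
#'   frame: strategy, fraction, category, mean, ci_low, ci_high, ses, tier),
#'   `summaries` (nested list of `capture_summary`), `inputs` and
#'   `manifest`. With `out_dir` set, writes `capture_report.csv`,
#'   `selection_sets.jsonl` and `manifest.json`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  inputs <- if (!is.null(config$synth)) {
    generate_synthetic_data(config$synth)
  } else {
    rec <- reconcile(read_tree_ensemble(config$trees_path),
                     read_species_table(config$species_path),
                     policy = "intersect")
    list(ensemble = rec$ensemble, table = rec$table)
  }
  ensemble <- inputs$ensemble
  table <- inputs$table
  seed <- config$seed

  if (config$threatened_only) {
    universe <- table$species[table$rl_category %in% RL_THREATENED]
    secured <- table$species[table$rl_category %in% RL_LOW_RISK]
  } else {
    universe <- table$species
    secured <- character(0)
  }
  if (length(universe) < 2L) stop("selection universe has fewer than 2 species")

  # per-species scores needed by rank strategies
  need_scores <- any(config$strategies %in% c("edge_rank", "ed_rank",
                                              "fdist_rank"))
  ed_med <- NULL
  if (need_scores) {
    ed <- ed_table(ensemble)
    ed_med <- stats::setNames(ed$ed_median, ed$species)
  }

  summaries <- list()
  sets_log <- list()
  cells <- list()
  for (f_i in seq_along(config$fractions)) {
    fraction <- config$fractions[[f_i]]
    k <- max(1L, round_half_up(fraction * length(universe)))
    per_strategy <- list()
    # fixed evaluation order so greedy templates exist before rl_controlled
    strategies <- intersect(SELECTION_STRATEGIES, config$strategies)
    for (strategy in strategies) {
      s_seed <- derive_seed(seed, 131L, f_i, match(strategy, SELECTION_STRATEGIES))
      results <- switch(
        strategy,
        greedy_pd = greedy_over_ensemble(
          ensemble, universe = universe, fraction = fraction,
          sets_per_tree = config$sets_per_tree, seed = s_seed),
        greedy_pd_threatened = greedy_over_ensemble(
          ensemble, universe = universe, fraction = fraction,
          sets_per_tree = config$sets_per_tree, secured = secured,
          seed = s_seed, strategy = "greedy_pd_threatened"),
        edge_rank = {
          et <- edge_table(ensemble, table)
          sc <- stats::setNames(et$edge_median, et$species)
          res <- rank_select(sc, intersect(universe, et$species), k,
                             strategy = "edge_rank")
          res$fraction <- fraction
          list(res)
        },
        ed_rank = {
          res <- rank_select(ed_med, universe, k, strategy = "ed_rank")
          res$fraction <- fraction
          list(res)
        },
        fdist_rank = {
          sc <- stats::setNames(table$fdist, table$species)
          res <- rank_select(sc, universe, k, strategy = "fdist_rank")
          res$fraction <- fraction
          list(res)
        },
        # stochastic strategies: `replicates` independent sets
        {
          template_pool <- per_strategy[["greedy_pd_threatened"]] %||%
            per_strategy[["greedy_pd"]]
          lapply(seq_len(config$replicates), function(r) {
            template <- if (strategy == "rl_controlled") {
              if (is.null(template_pool)) {
                stop("rl_controlled requires a greedy strategy in the same run")
              }
              template_pool[[1L + (r - 1L) %% length(template_pool)]]
            }
            draw_stochastic_set(strategy, universe, table, fraction, k,
                                template = template,
                                seed = derive_seed(s_seed, r), replicate = r)
          })
        }
      )
      per_strategy[[strategy]] <- results
    }
    for (strategy in strategies) {
      for (categ in config$categories) {
        obs <- capture_summary(per_strategy[[strategy]], table, categ)
        summaries[[as.character(fraction)]][[strategy]][[categ]] <- obs
        row <- data.frame(strategy = strategy, fraction = fraction,
                          category = categ, n_selected = k,
                          mean = obs$mean, ci_low = obs$ci95_low,
                          ci_high = obs$ci95_high,
                          ses = NA_real_, tier = NA_character_,
                          stringsAsFactors = FALSE)
        if (strategy != config$null_strategy &&
            config$null_strategy %in% config$strategies) {
          null_sum <- capture_summary(per_strategy[[config$null_strategy]],
                                      table, categ)
          rep <- tryCatch(ses_between(obs, null_sum), error = function(e) NULL)
          if (!is.null(rep)) {
            row$ses <- rep$ses
            row$tier <- rep$tier
          }
        }
        cells[[length(cells) + 1L]] <- row
      }
    }
    sets_log[[as.character(fraction)]] <- per_strategy
  }
  cells <- do.call(rbind, cells)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pdoption")),
    seed = config$seed,
    fractions = config$fractions,
    strategies = config$strategies,
    null_strategy = config$null_strategy,
    categories = config$categories,
    replicates = config$replicates,
    sets_per_tree = config$sets_per_tree,
    threatened_only = config$threatened_only,
    n_species = nrow(table),
    n_trees = length(ensemble$trees),
    universe_size = length(universe),
    synth = if (!is.null(config$synth)) unclass(config$synth),
    inputs = list(trees = config$trees_path, species = config$species_path)
  )
  out <- structure(
    list(cells = cells, summaries = summaries, sets = sets_log,
         inputs = inputs, manifest = manifest),
    class = "experiment_result"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cells, file.path(config$out_dir, "capture_report.csv"),
                     row.names = FALSE)
    write_sets_jsonl(sets_log,
                     file.path(config$out_dir, "selection_sets.jsonl"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One selection per line: strategy, fraction, tree_index, replicate, taxa.
write_sets_jsonl <- function(sets_log, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (fraction in names(sets_log)) {
    for (strategy in names(sets_log[[fraction]])) {
      for (res in sets_log[[fraction]][[strategy]]) {
        writeLines(jsonlite::toJSON(
          list(strategy = res$strategy, fraction = res$fraction,
               tree_index = res$tree_index, replicate = res$replicate,
               pd = res$pd_value, taxa = res$taxa),
          auto_unbox = TRUE, digits = NA, null = "null"), con)
      }
    }
  }
  invisible(path)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Capture experiment: %d cells (%d strategies x %d fractions x %d categories)\n",
              nrow(x$cells), length(x$manifest$strategies),
              length(x$manifest$fractions), length(x$manifest$categories)))
  invisible(x)
}
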