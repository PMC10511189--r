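# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Sample sizes are defined as a fixed fraction of a species universe;
#' fractional counts are rounded half-up (0.5 always rounds upwards), unlike
#' [base::round()]'s banker's rounding, so that published sample fractions map
#' to a single reproducible set size.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

# Deterministically mix a master seed with stream indices into a new seed in
# [0, 2^31 - 2]. All arithmetic stays below 2^53 so doubles are exact.
derive_seed <- function(seed, ...) {
  v <- c(seed, ...)
  h <- 0
  for (x in v) {
    h <- (h * 1000003 + (as.numeric(x) %% 2147483647)) %% 2147483647
  }
  h
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so seeded operations do not perturb the
# global stream.
with_seed <- function(seed, expr) {
  # force the seed BEFORE snapshotting the RNG state: evaluating it may
  # itself consume random numbers in the caller (e.g. derived seeds)
  seed <- as.integer(seed %% 2147483647)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Canonical tip/species label form: trimmed, underscores as spaces.
normalize_label <- function(x) {
  gsub("_", " ", trimws(x), fixed = TRUE)
}

#' Red List categories and extinction-risk groupings
#'
#' The closed Red List vocabulary used throughout: LC (least concern),
#' NT (near threatened), VU (vulnerable), EN (endangered), CR (critically
#' endangered), EW (extinct in the wild) and DD (data deficient).
#' Low-risk species are LC and NT; threatened species are VU, EN, CR and EW.
#'
#' @format Character vectors.
#' @name rl_categories
NULL

#' @rdname rl_categories
#' @export
RL_CATEGORIES <- c("LC", "NT", "VU", "EN", "CR", "EW", "DD")

#' @rdname rl_categories
#' @export
RL_THREATENED <- c("VU", "EN", "CR", "EW")

#' @rdname rl_categories
#' @export
RL_LOW_RISK <- c("LC", "NT")

# Utilization categories carried as use_* flag columns.
USE_CATEGORIES <- c("food", "materials", "medicine", "pets", "other")

use_flag_column <- function(category) paste0("use_", category)
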