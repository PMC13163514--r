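# Phenology-constrained selection of contrasting genotypes.

.as_bv <- function(x, trait = "trait") {
  if (inherits(x, "bv_set")) return(x)
  bv_set(x, trait = trait)
}

#' Phenology window: genotypes within m +/- h*s of the population mean
#'
#' Retains genotypes whose (predicted or observed) flowering value lies
#' within `half_width_sd` sample standard deviations of the population mean
#' (inclusive bounds). Restricting selection to this window targets drought
#' resistance rather than drought escape through very early flowering.
#' With `half_width_sd = 1` and Normally distributed values the retained
#' fraction converges to 2*pnorm(1) - 1 (about 68%).
#'
#' @param ft a [bv_set()] (or named numeric vector) of flowering values.
#' @param half_width_sd window half-width in SD units.
#' @return Named logical mask with attributes `m` and `s`.
#' @export
phenology_window <- function(ft, half_width_sd = 1) {
  if (half_width_sd <= 0) stop("half_width_sd must be positive")
  ft <- .as_bv(ft, "flowering")
  if (length(ft$values) < 2) stop("at least 2 genotypes are required")
  mask <- abs(ft$values - ft$m) <= half_width_sd * ft$s
  attr(mask, "m") <- ft$m
  attr(mask, "s") <- ft$s
  mask
}

#' Phenology window enforced across several environments
#'
#' A genotype passes only if it passes [phenology_window()] in EVERY supplied
#' environment (the window's `m` and `s` are environment-specific). Genotypes
#' absent from any environment are excluded with a warning.
#'
#' @param ft_by_env named list of per-environment [bv_set()]s (or named
#'   numeric vectors) of flowering values.
#' @param half_width_sd window half-width in SD units.
#' @return Named logical mask over the union of genotype ids.
#' @export
multi_environment_window <- function(ft_by_env, half_width_sd = 1) {
  if (length(ft_by_env) < 1) stop("at least one environment is required")
  ft_by_env <- lapply(ft_by_env, .as_bv)
  ids_list <- lapply(ft_by_env, function(b) names(b$values))
  all_ids <- Reduce(union, ids_list)
  common <- Reduce(intersect, ids_list)
  dropped <- setdiff(all_ids, common)
  if (length(dropped)) {
    warning(sprintf("%d genotype(s) absent from at least one environment were excluded",
                    length(dropped)))
  }
  mask <- stats::setNames(rep(FALSE, length(all_ids)), all_ids)
  pass <- rep(TRUE, length(common))
  for (b in ft_by_env) {
    w <- phenology_window(b, half_width_sd)
    pass <- pass & w[common]
  }
  mask[common] <- pass
  mask
}

#' Average breeding values across models
#'
#' Per-genotype arithmetic mean of several breeding-value sets for the same
#' trait over the same genotypes — e.g. averaging rrBLUP and weighted-GBLUP
#' predictions before selection. The mean and SD are recomputed.
#'
#' @param bv_sets list of [bv_set()]s with identical genotype id sets.
#' @return A [bv_set()].
#' @export
average_predictions <- function(bv_sets) {
  if (length(bv_sets) < 1) stop("at least one bv_set is required")
  bv_sets <- lapply(bv_sets, .as_bv)
  ids <- names(bv_sets[[1]]$values)
  for (b in bv_sets[-1]) {
    if (!setequal(names(b$values), ids)) {
      stop("breeding-value sets cover different genotype ids")
    }
  }
  vals <- rowMeans(vapply(bv_sets, function(b) b$values[ids],
                          numeric(length(ids))))
  bv_set(stats::setNames(vals, ids), trait = bv_sets[[1]]$trait)
}

#' Standardized lime-adaptation index
#'
#' Standardizes predicted yield and predicted lime-susceptibility score to
#' zero mean and unit SD, inverts the sign of the susceptibility z-score
#' (turning it into a tolerance score) and averages the two:
#' `index = (z_yield - z_susceptibility) / 2`. The index has zero mean.
#'
#' @param yield_bv,susceptibility_bv [bv_set()]s over matching genotype ids.
#' @return A [bv_set()] of index values (trait `"lime_adaptation"`).
#' @export
lime_adaptation_index <- function(yield_bv, susceptibility_bv) {
  yield_bv <- .as_bv(yield_bv, "yield")
  susceptibility_bv <- .as_bv(susceptibility_bv, "susceptibility")
  ids <- names(yield_bv$values)
  if (!setequal(names(susceptibility_bv$values), ids)) {
    stop("yield and susceptibility sets cover different genotype ids")
  }
  if (yield_bv$s == 0 || susceptibility_bv$s == 0) {
    stop("zero standard deviation: index undefined")
  }
  zy <- (yield_bv$values[ids] - yield_bv$m) / yield_bv$s
  zs <- (susceptibility_bv$values[ids] - susceptibility_bv$m) /
    susceptibility_bv$s
  bv_set(stats::setNames((zy - zs) / 2, ids), trait = "lime_adaptation")
}

#' Quartile/average mask on a secondary breeding-value set
#'
#' Secondary-site constraints used when selecting contrasting genotypes:
#' `"top_quartile"` keeps values at or above the 75th percentile,
#' `"below_average"` keeps values strictly below the mean, and
#' `"middle_quartiles"` keeps values in `[q25, q75)`. Percentiles use linear
#' interpolation between order statistics (default `quantile()` convention).
#'
#' @param secondary_bv a [bv_set()] (or named numeric vector).
#' @param rule one of `"top_quartile"`, `"below_average"`,
#'   `"middle_quartiles"`.
#' @return Named logical mask.
#' @export
quartile_mask <- function(secondary_bv,
                          rule = c("top_quartile", "below_average",
                                   "middle_quartiles")) {
  rule <- match.arg(rule)
  bv <- .as_bv(secondary_bv)
  x <- bv$values
  if (length(x) < 4) stop("at least 4 genotypes are required")
  switch(rule,
         top_quartile = x >= stats::quantile(x, 0.75, names = FALSE),
         below_average = x < mean(x),
         middle_quartiles = x >= stats::quantile(x, 0.25, names = FALSE) &
           x < stats::quantile(x, 0.75, names = FALSE))
}

#' Select predicted top-, mid- and bottom-performing genotypes
#'
#' Among the candidates (after any phenology mask), selects the genotype
#' with the highest predicted value (top), the lowest (bottom), and the one
#' closest to the mean of the candidates' predicted values (mid). Each role
#' can carry an additional secondary-site mask (e.g. quartile constraints on
#' a second environment's predictions). Ties break towards the
#' lexicographically smallest genotype id and are flagged.
#'
#' @param primary_bv a [bv_set()] of predicted values driving the selection.
#' @param candidate_mask optional named logical mask of admissible genotypes
#'   (e.g. from [phenology_window()]); `NULL` admits all.
#' @param secondary_masks optional named list with entries `top`, `mid`,
#'   `bottom`, each a named logical mask that the corresponding role must
#'   also satisfy.
#' @param mid_reference `"candidates"` (default) computes the mid-target
#'   mean over the phenology-admissible candidates; `"all"` uses every
#'   genotype in `primary_bv`.
#' @return A list of class `selection_decision`: `selected` (named ids),
#'   `index_values`, `candidate_mask`, `candidate_mean`, `ties` and
#'   `counts` (candidate counts after each constraint).
#' @export
select_contrasting <- function(primary_bv, candidate_mask = NULL,
                               secondary_masks = NULL,
                               mid_reference = c("candidates", "all")) {
  mid_reference <- match.arg(mid_reference)
  bv <- .as_bv(primary_bv)
  ids <- names(bv$values)
  if (is.null(candidate_mask)) {
    candidate_mask <- stats::setNames(rep(TRUE, length(ids)), ids)
  }
  cand <- ids[ids %in% names(candidate_mask)[candidate_mask]]
  if (length(cand) < 3) stop("fewer than 3 candidates after masking")
  counts <- c(total = length(ids), candidates = length(cand))
  role_pool <- function(role) {
    pool <- cand
    m <- secondary_masks[[role]]
    if (!is.null(m)) pool <- pool[pool %in% names(m)[m]]
    if (length(pool) == 0) {
      stop(sprintf("no candidate satisfies the '%s' secondary constraint", role))
    }
    pool
  }
  pick <- function(pool, score) {
    best <- pool[score == max(score)]
    list(id = sort(best)[1], tie = length(best) > 1)
  }
  vals <- bv$values
  ref_mean <- mean(vals[if (mid_reference == "candidates") cand else ids])
  top_pool <- role_pool("top")
  mid_pool <- role_pool("mid")
  bottom_pool <- role_pool("bottom")
  counts <- c(counts, top_pool = length(top_pool), mid_pool = length(mid_pool),
              bottom_pool = length(bottom_pool))
  top <- pick(top_pool, vals[top_pool])
  bottom_pool <- setdiff(bottom_pool, top$id)
  if (length(bottom_pool) == 0) {
    stop("no candidate satisfies the 'bottom' secondary constraint")
  }
  bottom <- pick(bottom_pool, -vals[bottom_pool])
  mid_pool <- setdiff(mid_pool, c(top$id, bottom$id))
  if (length(mid_pool) == 0) {
    stop("no candidate satisfies the 'mid' secondary constraint")
  }
  mid <- pick(mid_pool, -abs(vals[mid_pool] - ref_mean))
  structure(list(
    selected = c(top = top$id, mid = mid$id, bottom = bottom$id),
    index_values = vals,
    candidate_mask = stats::setNames(ids %in% cand, ids),
    candidate_mean = ref_mean,
    ties = c(top = top$tie, mid = mid$tie, bottom = bottom$tie),
    counts = counts
  ), class = "selection_decision")
}

#' @export
print.selection_decision <- function(x, ...) {
  v <- x$index_values[x$selected]
  cat(sprintf("selection: top = %s (%.3g), mid = %s (%.3g), bottom = %s (%.3g)\n",
              x$selected["top"], v[1], x$selected["mid"], v[2],
              x$selected["bottom"], v[3]))
  cat(sprintf("candidates: %d of %d genotypes\n", x$counts["candidates"],
              x$counts["total"]))
  invisible(x)
}
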