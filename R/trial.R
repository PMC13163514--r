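# Managed-environment trial analytics: water budgets, factorial ANOVA with
# block-within-environment error terms, LSD mean separation, crossover GEI.

#' Water budget of a managed-environment pair
#'
#' Water received (mm) before sowing (`bs`), from sowing to treatment
#' application (`sa`), and during treatment application under the stress
#' (`ds`) and moisture-favorable (`mf`) regimes.
#'
#' @param bs,sa,ds,mf non-negative amounts in mm.
#' @return A list of class `water_budget`.
#' @export
water_budget <- function(bs, sa, ds, mf) {
  vals <- c(bs = bs, sa = sa, ds = ds, mf = mf)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("water amounts must be non-negative")
  }
  structure(as.list(vals), class = "water_budget")
}

#' Percent reduction in total water under the stress treatment
#'
#' `round(100 * (1 - (bs + sa + ds) / (bs + sa + mf)))`: the reduction in the
#' total amount of water received in the stress treatment relative to the
#' moisture-favorable one, rounded to the nearest whole percent.
#'
#' @param budget a [water_budget()].
#' @return Integer percent.
#' @export
water_reduction_pct <- function(budget) {
  stopifnot(inherits(budget, "water_budget"))
  fav <- budget$bs + budget$sa + budget$mf
  if (fav <= 0) stop("favorable-treatment water total must be positive")
  stress <- budget$bs + budget$sa + budget$ds
  as.integer(round(100 * (1 - stress / fav)))
}

#' Harvest index
#'
#' Grain dry weight divided by total above-ground dry weight
#' (grain + straw), per plot. Vectorised.
#'
#' @param grain,straw non-negative dry weights (t/ha).
#' @return Fraction in \[0, 1\].
#' @export
harvest_index <- function(grain, straw) {
  if (any(grain < 0) || any(straw < 0)) stop("weights must be non-negative")
  tot <- grain + straw
  if (any(tot == 0)) stop("grain + straw must be positive")
  grain / tot
}

#' Plant density of the plot geometry
#'
#' Plants per square metre implied by the plot layout, rounded to an
#' integer. Defaults reproduce the standard managed-environment plot:
#' six rows of four plants on a 0.90 m x 0.80 m plot, i.e. 33 plants/m2.
#'
#' @param rows,plants_per_row plants layout.
#' @param row_spacing_m,plant_spacing_m spacings in metres (geometry
#'   metadata; the density uses the plot envelope).
#' @param plot_w_m,plot_l_m plot width and length in metres.
#' @return Integer plants per m2.
#' @export
plant_density <- function(rows = 6, row_spacing_m = 0.15, plants_per_row = 4,
                          plant_spacing_m = 0.20, plot_w_m = 0.90,
                          plot_l_m = 0.80) {
  if (any(c(rows, plants_per_row, row_spacing_m, plant_spacing_m,
            plot_w_m, plot_l_m) <= 0)) {
    stop("plot dimensions and counts must be positive")
  }
  as.integer(round(rows * plants_per_row / (plot_w_m * plot_l_m)))
}

#' Least significant difference
#'
#' `t(1 - alpha/2, df_error) * sqrt(2 * ms_error / n_per_mean)`: the smallest
#' difference between two means (each averaging `n_per_mean` plots) declared
#' significant at level `alpha`.
#'
#' @param ms_error error mean square of the declared error term.
#' @param df_error its degrees of freedom.
#' @param n_per_mean plots averaged into each mean (e.g. 8 for genotype
#'   means over 4 blocks x 2 soil types, 4 for single-condition means).
#' @param alpha significance level.
#' @return LSD in trait units.
#' @export
lsd_value <- function(ms_error, df_error, n_per_mean, alpha = 0.05) {
  if (ms_error < 0) stop("ms_error must be non-negative")
  if (df_error < 1) stop("df_error must be at least 1")
  if (n_per_mean < 1) stop("n_per_mean must be at least 1")
  stats::qt(1 - alpha / 2, df_error) * sqrt(2 * ms_error / n_per_mean)
}

# Letter groupings for means separated by a common LSD: descending-mean
# sweep; means differing by >= lsd share no letter (a difference of exactly
# lsd is significant).
.lsd_letters <- function(means, lsd) {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  sorted <- means[ord]
  groups <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && sorted[i] - sorted[j + 1] < lsd) j <- j + 1
    groups[[length(groups) + 1L]] <- i:j
  }
  # keep maximal groups only
  keep <- vapply(seq_along(groups), function(a) {
    !any(vapply(seq_along(groups), function(b) {
      a != b && all(groups[[a]] %in% groups[[b]])
    }, logical(1)))
  }, logical(1))
  groups <- unique(groups[keep])
  lett <- rep("", k)
  for (gi in seq_along(groups)) {
    lett[groups[[gi]]] <- paste0(lett[groups[[gi]]], letters[gi])
  }
  out <- rep("", k)
  out[ord] <- lett
  out
}

.plots_subset <- function(plots, trait) {
  need <- c("genotype", "water", "soil", "block", "trait", "value")
  if (!all(need %in% names(plots))) {
    stop("plot data must have columns: ", paste(need, collapse = ", "))
  }
  d <- plots[plots$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stop(sprintf("no observations for trait '%s'", trait))
  d$water <- factor(d$water, levels = WATER_LEVELS)
  d$soil <- factor(d$soil, levels = SOIL_TYPES)
  if (anyNA(d$water) || anyNA(d$soil)) {
    stop("water/soil levels must be drought|favorable and sandy_loam|silty_clay")
  }
  d$genotype <- factor(d$genotype)
  d$block <- factor(d$block)
  d
}

.check_balance <- function(d) {
  counts <- table(d$genotype, d$water, d$soil, d$block)
  if (length(unique(as.vector(counts))) != 1L || counts[1] < 1) {
    bad <- which(counts == 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("unbalanced design: empty cell genotype=%s water=%s soil=%s block=%s",
                   dimnames(counts)[[1]][bad[1, 1]], dimnames(counts)[[2]][bad[1, 2]],
                   dimnames(counts)[[3]][bad[1, 3]], dimnames(counts)[[4]][bad[1, 4]]))
    }
    stop("unbalanced design: unequal cell counts")
  }
  invisible(counts[1])
}

#' Partitioned factorial ANOVA with block-within-environment error terms
#'
#' Balanced ANOVA for a genotype x water x soil factorial laid out as a
#' randomized complete block design within each of the four environments
#' (water x soil combinations). The environment variation and its
#' interaction with genotypes are partitioned into water amount, soil type
#' and water x soil sources. Water, soil and water x soil are tested against
#' the block-within-environment mean square; genotype and all
#' genotype-involving interactions are tested against the residual.
#'
#' @param plots long-format plot data (`genotype`, `water`, `soil`, `block`,
#'   `trait`, `value`).
#' @param trait trait to analyse.
#' @return A `data.frame` of class `anova_table` with columns `source`, `df`,
#'   `ss`, `ms`, `f`, `p`, `error_term`.
#' @export
anova_partitioned <- function(plots, trait) {
  d <- .plots_subset(plots, trait)
  .check_balance(d)
  fit <- stats::aov(value ~ water * soil + water:soil:block + genotype +
                      genotype:water + genotype:soil + genotype:water:soil,
                    data = d)
  ss_tab <- summary(fit)[[1]]
  rn <- trimws(rownames(ss_tab))
  grab <- function(term) {
    i <- match(term, rn)
    if (is.na(i)) stop("missing ANOVA term: ", term)
    c(df = ss_tab[i, "Df"], ss = ss_tab[i, "Sum Sq"])
  }
  terms <- list(
    genotype = grab("genotype"),
    water = grab("water"),
    soil = grab("soil"),
    `water x soil` = grab("water:soil"),
    `block(environment)` = grab("water:soil:block"),
    `genotype x water` = grab("water:genotype"),
    `genotype x soil` = grab("soil:genotype"),
    `genotype x water x soil` = grab("water:soil:genotype"),
    residual = grab("Residuals")
  )
  tab <- data.frame(
    source = names(terms),
    df = vapply(terms, `[[`, numeric(1), "df"),
    ss = vapply(terms, `[[`, numeric(1), "ss"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab$ms <- tab$ss / tab$df
  ms_block <- tab$ms[tab$source == "block(environment)"]
  df_block <- tab$df[tab$source == "block(environment)"]
  ms_res <- tab$ms[tab$source == "residual"]
  df_res <- tab$df[tab$source == "residual"]
  err <- c(genotype = "residual", water = "block(environment)",
           soil = "block(environment)", `water x soil` = "block(environment)",
           `block(environment)` = NA, `genotype x water` = "residual",
           `genotype x soil` = "residual",
           `genotype x water x soil` = "residual", residual = NA)
  tab$f <- NA_real_
  tab$p <- NA_real_
  for (i in seq_len(nrow(tab))) {
    e <- err[[tab$source[i]]]
    if (is.na(e)) next
    ms_e <- if (e == "residual") ms_res else ms_block
    df_e <- if (e == "residual") df_res else df_block
    tab$f[i] <- tab$ms[i] / ms_e
    tab$p[i] <- stats::pf(tab$f[i], tab$df[i], df_e, lower.tail = FALSE)
  }
  tab$error_term <- unname(err[tab$source])
  class(tab) <- c("anova_table", "data.frame")
  attr(tab, "trait") <- trait
  tab
}

#' Environment mean comparison with LSD letters
#'
#' Means of the four managed environments (water x soil cells) across
#' genotypes and blocks, separated by the LSD computed from the
#' block-within-environment mean square — the declared error term for
#' environment contrasts.
#'
#' @param plots long-format plot data.
#' @param trait trait to summarise.
#' @param alpha significance level for the LSD.
#' @return A `data.frame` of class `mean_comparison` (`water`, `soil`,
#'   `mean`, `letters`) with attributes `lsd`, `ms_error`, `df_error`,
#'   `n_per_mean`.
#' @export
environment_means <- function(plots, trait, alpha = 0.05) {
  d <- .plots_subset(plots, trait)
  .check_balance(d)
  tab <- anova_partitioned(plots, trait)
  ms_block <- tab$ms[tab$source == "block(environment)"]
  df_block <- tab$df[tab$source == "block(environment)"]
  agg <- stats::aggregate(value ~ water + soil, data = d, FUN = mean)
  n_per_mean <- nlevels(d$genotype) * nlevels(d$block)
  lsd <- lsd_value(ms_block, df_block, n_per_mean, alpha)
  agg$letters <- .lsd_letters(agg$value, lsd)
  names(agg)[names(agg) == "value"] <- "mean"
  agg <- agg[order(-agg$mean), ]
  rownames(agg) <- NULL
  class(agg) <- c("mean_comparison", "data.frame")
  attr(agg, "lsd") <- lsd
  attr(agg, "ms_error") <- ms_block
  attr(agg, "df_error") <- df_block
  attr(agg, "n_per_mean") <- n_per_mean
  agg
}

#' Percent yield reduction along the water or soil axis
#'
#' Averages the two stressed-level environment means and the two
#' favorable-level means along the chosen axis and reports
#' `round(100 * (1 - stressed/favorable))`. The stressed levels are
#' `drought` (water axis) and `silty_clay` (moderately calcareous soil
#' axis).
#'
#' @param env_means a [environment_means()] result, or any data frame with
#'   columns `water`, `soil`, `mean` covering the four environments.
#' @param axis `"water"` or `"soil"`.
#' @return Integer percent reduction.
#' @export
stress_reduction_pct <- function(env_means, axis = c("water", "soil")) {
  axis <- match.arg(axis)
  need <- c("water", "soil", "mean")
  if (!all(need %in% names(env_means))) {
    stop("env_means must have columns water, soil, mean")
  }
  if (nrow(env_means) != 4) stop("all four environment means are required")
  if (axis == "water") {
    stressed <- mean(env_means$mean[env_means$water == "drought"])
    fav <- mean(env_means$mean[env_means$water == "favorable"])
  } else {
    stressed <- mean(env_means$mean[env_means$soil == "silty_clay"])
    fav <- mean(env_means$mean[env_means$soil == "sandy_loam"])
  }
  if (is.na(stressed) || is.na(fav)) stop("missing environment level")
  if (fav == 0) stop("favorable mean is zero; reduction undefined")
  as.integer(round(100 * (1 - stressed / fav)))
}

#' Detect significant crossover genotype-by-environment interactions
#'
#' Reports every genotype pair whose mean difference changes sign between
#' the two conditions while both differences reach the condition's LSD —
#' i.e. rank-reversing (crossover) GEI that is significant in both
#' conditions.
#'
#' @param genotype_by_condition_means genotypes x 2 numeric matrix of means
#'   (rownames = genotype ids, colnames = conditions).
#' @param lsd LSD threshold(s): one value, or one per condition.
#' @return A `data.frame` with columns `genotype_1`, `genotype_2`,
#'   `condition_1`, `condition_2`, `diff_1`, `diff_2` (possibly 0 rows).
#' @export
detect_crossover <- function(genotype_by_condition_means, lsd) {
  m <- as.matrix(genotype_by_condition_means)
  if (ncol(m) != 2) stop("exactly 2 conditions are required")
  if (nrow(m) < 2) stop("at least 2 genotypes are required")
  if (length(lsd) == 1) lsd <- rep(lsd, 2)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("G", seq_len(nrow(m)))
  conds <- colnames(m)
  if (is.null(conds)) conds <- c("condition_1", "condition_2")
  out <- list()
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      d1 <- m[i, 1] - m[j, 1]
      d2 <- m[i, 2] - m[j, 2]
      if (sign(d1) * sign(d2) == -1 && abs(d1) >= lsd[1] && abs(d2) >= lsd[2]) {
        out[[length(out) + 1L]] <- data.frame(
          genotype_1 = ids[i], genotype_2 = ids[j],
          condition_1 = conds[1], condition_2 = conds[2],
          diff_1 = d1, diff_2 = d2, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(genotype_1 = character(0), genotype_2 = character(0),
                      condition_1 = character(0), condition_2 = character(0),
                      diff_1 = numeric(0), diff_2 = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Genotype means by condition
#'
#' Convenience aggregation of plot data into a genotypes x levels matrix of
#' means along one factor (averaging over the other factor and blocks) —
#' the input shape expected by [detect_crossover()].
#'
#' @param plots long-format plot data.
#' @param trait trait to aggregate.
#' @param by `"water"` or `"soil"`.
#' @return Numeric matrix, genotypes x factor levels.
#' @export
genotype_condition_means <- function(plots, trait, by = c("water", "soil")) {
  by <- match.arg(by)
  d <- .plots_subset(plots, trait)
  agg <- stats::aggregate(d$value, by = list(genotype = d$genotype,
                                             cond = d[[by]]), FUN = mean)
  lev <- levels(d[[by]])
  ids <- levels(d$genotype)
  m <- matrix(NA_real_, length(ids), length(lev), dimnames = list(ids, lev))
  m[cbind(match(agg$genotype, ids), match(agg$cond, lev))] <- agg$x
  m
}

#' Write an ANOVA table or mean comparison as CSV
#'
#' @param x an `anova_table` or `mean_comparison`.
#' @param path file path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
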