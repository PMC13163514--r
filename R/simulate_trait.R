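# Trait architectures, trial simulation and GBS noise.

# Per-trait calibration of the trial generator: cell means for the four
# managed environments (2 water x 2 soil) on realistic white lupin scales
# (yields in t/ha, phenology in days from 1 April, height in cm, seed weight
# in g), plus each trait's characteristic plot-error scale relative to grain
# yield. Harvest index is derived per plot from grain and straw, never
# simulated directly.
.trait_table <- function() {
  data.frame(
    trait = c("grain_yield", "straw", "flowering", "maturity", "height",
              "seed_weight"),
    drought_sandy_loam = c(3.67, 4.33, 15.7, 76.8, 102.5, 0.33),
    drought_silty_clay = c(2.63, 2.55, 15.7, 82.8, 72.3, 0.33),
    favorable_sandy_loam = c(4.31, 5.19, 16.1, 81.3, 108.7, 0.33),
    favorable_silty_clay = c(3.49, 4.44, 16.3, 90.3, 92.1, 0.33),
    err_scale = c(0.35, 0.53, 0.60, 1.00, 3.50, 0.013) / 0.35,
    stringsAsFactors = FALSE
  )
}

WATER_LEVELS <- c("drought", "favorable")
SOIL_TYPES <- c("sandy_loam", "silty_clay")

#' Simulate an additive trait architecture
#'
#' Draws a sparse vector of additive marker effects over `qtl_count` loci.
#' For the flowering trait, `major_gene_count` of the QTL receive large
#' effects scaled so that together they explain at least half of the genetic
#' variance, reflecting the major-gene control of flowering time in white
#' lupin; all other traits are polygenic with standard-normal QTL effects.
#'
#' @param config a [simulation_config()].
#' @param trait trait name; `"flowering"` triggers the major-gene layout.
#' @return A list of class `trait_architecture` with elements `trait`,
#'   `effects` (length `n_markers`), `qtl` (QTL indices) and `major`
#'   (major-gene indices, possibly empty).
#' @export
simulate_trait_architecture <- function(config, trait) {
  q <- config$qtl_count
  p <- config$n_markers
  if (q > p) stop("qtl_count exceeds n_markers")
  .with_seed(.derive_seed(config$seed, paste0("architecture_", trait)), {
    effects <- numeric(p)
    qtl <- integer(0)
    major <- integer(0)
    if (q > 0) {
      qtl <- sort(sample.int(p, q))
      effects[qtl] <- stats::rnorm(q)
      if (identical(trait, "flowering") && config$major_gene_count > 0) {
        mg <- min(config$major_gene_count, q)
        major <- qtl[seq_len(mg)]
        n_minor <- q - mg
        # majors carry ~3x the minors' summed variance => >= 50% share
        amp <- sqrt(3 * max(n_minor, 1) / mg)
        effects[major] <- amp * sign(stats::rnorm(mg) + 0.5)
      }
    }
    structure(list(trait = trait, effects = effects, qtl = qtl, major = major),
              class = "trait_architecture")
  })
}

# Scale raw genetic values (dosage %*% effects) to the genetic SD implied by
# the target genotype-mean heritability, the plot error SD and block count.
.scaled_genetic_values <- function(geno, arch, h2, err_sd, blocks, unit = 1) {
  raw <- as.numeric(geno$dosage %*% arch$effects)
  s <- stats::sd(raw)
  if (is.na(s) || s == 0) return(rep(0, length(raw)))
  target_sd <- if (err_sd == 0 || h2 >= 1) {
    0.2 * unit  # noise-free / h2 = 1 runs keep a fixed trait-scale genetic SD
  } else {
    sqrt(h2 / (1 - h2) * err_sd^2 / blocks)
  }
  (raw - mean(raw)) / s * target_sd
}

#' Simulate a 2 water x 2 soil randomized complete block trial
#'
#' Generates plot-level records for every genotype in all four managed
#' environments (drought/favorable x sandy-loam/silty-clay) with `blocks`
#' complete blocks per environment. The plot model is
#' `value = cell_mean(water, soil) + g + s_w*c_w + s_s*c_s + s_ws*c_w*c_s +
#' block(env) + e`, where `g` is the genotype's additive genetic value
#' (scaled to the configured heritability) and the `s` terms are
#' genotype-specific environmental sensitivities (GEI). `crossover_pairs`
#' genotype pairs receive equal genetic values and opposite water
#' sensitivities of magnitude `crossover_delta`, implanting rank-reversing
#' GEI that exceeds the trial's LSD. Yields are truncated at zero and
#' harvest index is derived per plot when grain and straw are both present.
#'
#' @param geno a [genotype_matrix()].
#' @param architectures named list of [simulate_trait_architecture()] results
#'   covering every requested trait.
#' @param config a [simulation_config()].
#' @param blocks replicate blocks per environment.
#' @param traits traits to simulate (default: all architectures supplied).
#' @return A long-format `data.frame` with columns `genotype`, `water`,
#'   `soil`, `block`, `trait`, `value`. Attributes: `genetic_values`
#'   (genotype x trait matrix), `sensitivities` (per-trait list) and
#'   `crossover_pairs` (data.frame of implanted pairs).
#' @export
simulate_trial <- function(geno, architectures, config, blocks = 4L,
                           traits = names(architectures)) {
  .assert_count(blocks, "blocks")
  missing_arch <- setdiff(traits, names(architectures))
  if (length(missing_arch)) {
    stop("no architecture supplied for trait(s): ",
         paste(missing_arch, collapse = ", "))
  }
  tt <- .trait_table()
  unknown <- setdiff(traits, tt$trait)
  if (length(unknown)) {
    stop("unknown trait(s): ", paste(unknown, collapse = ", "))
  }
  ids <- genotype_ids(geno)
  n <- length(ids)
  .with_seed(.derive_seed(config$seed, "trial"), {
    design <- expand.grid(genotype = ids, water = WATER_LEVELS,
                          soil = SOIL_TYPES, block = seq_len(blocks),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    c_w <- ifelse(design$water == "drought", -1, 1)
    c_s <- ifelse(design$soil == "sandy_loam", 1, -1)
    env <- paste(design$water, design$soil, sep = "/")
    gv_mat <- matrix(0, n, length(traits), dimnames = list(ids, traits))
    sens <- list()
    pieces <- vector("list", length(traits))
    # implanted crossover pairs: consecutive genotypes at the head of the list
    n_pairs <- min(config$crossover_pairs, n %/% 2L)
    pair_df <- if (n_pairs > 0) {
      data.frame(genotype_fav = ids[2 * seq_len(n_pairs) - 1L],
                 genotype_drought = ids[2 * seq_len(n_pairs)],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(genotype_fav = character(0), genotype_drought = character(0))
    }
    gi <- match(design$genotype, ids)
    for (ti in seq_along(traits)) {
      trait <- traits[ti]
      row <- tt[tt$trait == trait, ]
      scale <- row$err_scale
      err_sd <- config$plot_error_sd * scale
      h2 <- if (trait %in% names(config$heritability)) {
        config$heritability[[trait]]
      } else {
        0.6
      }
      g <- .scaled_genetic_values(geno, architectures[[trait]], h2, err_sd,
                                  blocks, unit = scale)
      s_w <- stats::rnorm(n, 0, config$gei_sd_water * scale)
      s_s <- stats::rnorm(n, 0, config$gei_sd_soil * scale)
      s_ws <- stats::rnorm(n, 0, config$gei_sd_interaction * scale)
      if (trait == "grain_yield" && n_pairs > 0) {
        for (k in seq_len(n_pairs)) {
          i <- 2L * k - 1L
          j <- 2L * k
          g[j] <- g[i]
          s_s[j] <- s_s[i]
          s_ws[j] <- s_ws[i]
          s_w[i] <- config$crossover_delta   # better when favorable (+1)
          s_w[j] <- -config$crossover_delta  # better under drought (-1)
        }
      }
      gv_mat[, ti] <- g
      sens[[trait]] <- data.frame(genotype = ids, water = s_w, soil = s_s,
                                  interaction = s_ws)
      cell <- ifelse(design$water == "drought",
                     ifelse(design$soil == "sandy_loam",
                            row$drought_sandy_loam, row$drought_silty_clay),
                     ifelse(design$soil == "sandy_loam",
                            row$favorable_sandy_loam, row$favorable_silty_clay))
      blk_eff <- stats::rnorm(4L * blocks, 0, config$block_sd * scale)
      names(blk_eff) <- paste(rep(unique(env), each = blocks),
                              rep(seq_len(blocks), times = 4L))
      b <- blk_eff[paste(env, design$block)]
      e <- stats::rnorm(nrow(design), 0, err_sd)
      value <- cell + g[gi] + s_w[gi] * c_w + s_s[gi] * c_s +
        s_ws[gi] * c_w * c_s + b + e
      if (trait %in% c("grain_yield", "straw")) value <- pmax(value, 0)
      pieces[[ti]] <- data.frame(design, trait = trait, value = value,
                                 stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, pieces)
    if (all(c("grain_yield", "straw") %in% traits)) {
      gy <- pieces[[match("grain_yield", traits)]]
      st <- pieces[[match("straw", traits)]]
      tot <- gy$value + st$value
      hi <- ifelse(tot > 0, gy$value / tot, NA_real_)
      out <- rbind(out, data.frame(gy[, c("genotype", "water", "soil", "block")],
                                   trait = "harvest_index", value = hi,
                                   stringsAsFactors = FALSE))
    }
    rownames(out) <- NULL
    attr(out, "genetic_values") <- gv_mat
    attr(out, "sensitivities") <- sens
    attr(out, "crossover_pairs") <- pair_df
    out
  })
}

#' Inject GBS-like missingness and heterozygous miscalls
#'
#' Adds per-marker and per-genotype missing calls at rates drawn from the
#' configured ranges, plus heterozygous miscalls of homozygous calls at
#' `het_rate`. Designated "bad" markers/genotypes can be forced above the
#' standard QC thresholds (missing rate per marker >= 0.3, per genotype
#' >= 0.5, marker heterozygosity >= 0.3) so that downstream filters are
#' exercised: for those items an exact count of cells is masked, guaranteeing
#' the observed rate meets the drawn target rate.
#'
#' @param geno a [genotype_matrix()].
#' @param config a [simulation_config()]; supplies the base rates and seed.
#' @param bad_markers marker ids or indices to push over the marker
#'   missing-rate threshold.
#' @param bad_marker_rate_range range of forced per-marker missing rates.
#' @param bad_genotypes genotype ids or indices to push over the genotype
#'   missing-rate threshold.
#' @param bad_genotype_rate_range range of forced per-genotype missing rates.
#' @param bad_het_markers marker ids or indices to push over the
#'   heterozygosity threshold.
#' @param bad_het_rate target heterozygous fraction for those markers.
#' @return A [genotype_matrix()] with the same dimensions.
#' @export
add_gbs_noise <- function(geno, config,
                          bad_markers = NULL,
                          bad_marker_rate_range = c(0.4, 0.5),
                          bad_genotypes = NULL,
                          bad_genotype_rate_range = c(0.6, 0.7),
                          bad_het_markers = NULL,
                          bad_het_rate = 0.4) {
  .assert_fraction(config$missing_rate_marker_range, "missing_rate_marker_range")
  .assert_fraction(config$missing_rate_genotype_range, "missing_rate_genotype_range")
  .assert_fraction(config$het_rate, "het_rate")
  .assert_fraction(bad_marker_rate_range, "bad_marker_rate_range")
  .assert_fraction(bad_genotype_rate_range, "bad_genotype_rate_range")
  .assert_fraction(bad_het_rate, "bad_het_rate")
  X <- geno$dosage
  n <- nrow(X)
  p <- ncol(X)
  no_noise <- all(config$missing_rate_marker_range == 0) &&
    all(config$missing_rate_genotype_range == 0) &&
    config$het_rate == 0 && is.null(bad_markers) && is.null(bad_genotypes) &&
    is.null(bad_het_markers)
  if (no_noise) return(geno)
  if (is.character(bad_markers)) bad_markers <- match(bad_markers, marker_ids(geno))
  if (is.character(bad_genotypes)) bad_genotypes <- match(bad_genotypes, genotype_ids(geno))
  if (is.character(bad_het_markers)) bad_het_markers <- match(bad_het_markers, marker_ids(geno))
  .with_seed(.derive_seed(config$seed, "gbs_noise"), {
    mr <- stats::runif(p, config$missing_rate_marker_range[1],
                       config$missing_rate_marker_range[2])
    gr <- stats::runif(n, config$missing_rate_genotype_range[1],
                       config$missing_rate_genotype_range[2])
    # combined per-entry missingness from the two independent mechanisms
    pmiss <- 1 - outer(1 - gr, 1 - mr)
    miss <- matrix(stats::runif(n * p), n, p) < pmiss
    # heterozygous miscalls of observed homozygotes
    if (config$het_rate > 0) {
      flip <- matrix(stats::runif(n * p), n, p) < config$het_rate & X != 1
      X[flip & !miss] <- 1
    }
    X[miss] <- NA
    for (k in bad_markers) {
      rate <- stats::runif(1, bad_marker_rate_range[1], bad_marker_rate_range[2])
      rows <- sample.int(n, ceiling(rate * n))
      X[rows, k] <- NA
    }
    for (i in bad_genotypes) {
      rate <- stats::runif(1, bad_genotype_rate_range[1], bad_genotype_rate_range[2])
      cols <- sample.int(p, ceiling(rate * p))
      X[i, cols] <- NA
    }
    for (k in bad_het_markers) {
      obs <- which(!is.na(X[, k]))
      n_het <- ceiling(bad_het_rate * length(obs))
      X[obs[sample.int(length(obs), min(n_het, length(obs)))], k] <- 1
    }
    genotype_matrix(X, chrom = geno$chrom, pos = geno$pos)
  })
}

#' Write plot observations as tidy CSV
#'
#' @param plots long-format plot data as returned by [simulate_trial()].
#' @param path file path.
#' @export
write_plot_csv <- function(plots, path) {
  utils::write.csv(plots[, c("genotype", "water", "soil", "block", "trait",
                             "value")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
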