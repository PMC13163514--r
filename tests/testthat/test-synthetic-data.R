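# Population, trait and trial generators.

test_that("factorial cross population has the designed family structure", {
  cfg <- simulation_config(seed = 2, n_markers = 200)
  pop <- simulate_factorial_cross_population(cfg, lines_per_cross = 45)
  expect_equal(nrow(pop$dosage), 720)           # 4 x 4 x 45
  expect_equal(length(unique(attr(pop, "cross"))), 16)
  expect_true(all(table(attr(pop, "cross")) == 45))
  expect_true(all(pop$dosage %in% c(0, 1, 2)))
  # identical config => byte-identical matrices
  pop2 <- simulate_factorial_cross_population(cfg, lines_per_cross = 45)
  expect_identical(pop$dosage, pop2$dosage)
  expect_error(simulate_factorial_cross_population(cfg, lines_per_cross = 0),
               "positive")
})

test_that("residual heterozygosity matches the single-seed-descent expectation", {
  # among loci segregating within a cross, P(het) after g selfing
  # generations is (1/2)^g; pooled over seeds the observed fraction must sit
  # within 3 binomial SE of 1/32 for g = 5
  het_calls <- 0
  seg_calls <- 0
  for (seed in 1:10) {
    cfg <- simulation_config(seed = seed, n_markers = 150)
    pop <- simulate_factorial_cross_population(cfg, n_parents_a = 2,
                                               n_parents_b = 2,
                                               lines_per_cross = 40,
                                               inbreeding_generations = 5)
    parents <- attr(pop, "parents")
    cross <- attr(pop, "cross")
    for (cr in unique(cross)) {
      ab <- as.integer(sub("A(\\d+)xB(\\d+)", "\\1", cr))
      bb <- as.integer(sub("A(\\d+)xB(\\d+)", "\\2", cr))
      seg <- parents[ab, ] != parents[2 + bb, ]
      sub <- pop$dosage[cross == cr, seg, drop = FALSE]
      het_calls <- het_calls + sum(sub == 1)
      seg_calls <- seg_calls + length(sub)
    }
  }
  p_hat <- het_calls / seg_calls
  se <- sqrt((1 / 32) * (31 / 32) / seg_calls)
  expect_lt(abs(p_hat - 1 / 32), 3 * se)
})

test_that("landrace collection reproduces accession-level relatedness", {
  cfg <- simulation_config(seed = 4, n_markers = 150)
  pop <- simulate_landrace_collection(cfg)
  expect_equal(nrow(pop$dosage), 452)            # 113 accessions x 4
  expect_equal(length(unique(attr(pop, "accession"))), 113)

  within_v <- c()
  between_v <- c()
  for (seed in 1:5) {
    cfg <- simulation_config(seed = seed, n_markers = 120)
    pop <- simulate_landrace_collection(cfg, n_accessions = 12,
                                        genotypes_per_accession = 4)
    acc <- attr(pop, "accession")
    X <- pop$dosage
    n <- nrow(X)
    identity <- function(i, j) mean(X[i, ] == X[j, ])
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (acc[i] == acc[j]) within_v <- c(within_v, identity(i, j))
        else between_v <- c(between_v, identity(i, j))
      }
    }
  }
  expect_gt(mean(within_v), mean(between_v))
})

test_that("trait architectures are sparse, seeded, and major-gene aware", {
  cfg <- simulation_config(seed = 5, n_markers = 300, qtl_count = 40,
                           major_gene_count = 2)
  sparse <- simulate_trait_architecture(
    simulation_config(seed = 5, n_markers = 300, qtl_count = 1), "height")
  expect_equal(sum(sparse$effects != 0), 1)
  expect_error(simulate_trait_architecture(
    simulation_config(seed = 5, n_markers = 10, qtl_count = 11), "height"),
    "exceeds")

  arch0 <- simulation_config(seed = 9, n_markers = 100, qtl_count = 0)
  expect_identical(simulate_trait_architecture(arch0, "height")$effects,
                   numeric(100))

  # flowering major genes carry >= 50% of the genetic variance realized on a
  # simulated population (variance decomposition oracle)
  fl <- simulate_trait_architecture(cfg, "flowering")
  expect_length(fl$major, 2)
  pop <- simulate_factorial_cross_population(cfg, lines_per_cross = 20)
  g_all <- as.numeric(pop$dosage %*% fl$effects)
  eff_major <- fl$effects
  eff_major[setdiff(seq_along(eff_major), fl$major)] <- 0
  g_major <- as.numeric(pop$dosage %*% eff_major)
  expect_gte(var(g_major) / var(g_all), 0.5)

  fl2 <- simulate_trait_architecture(cfg, "flowering")
  expect_identical(fl$qtl, fl2$qtl)
  expect_identical(fl$effects, fl2$effects)
})

test_that("trial simulator honours the noise-free limit", {
  cfg <- simulation_config(seed = 6, n_markers = 120, plot_error_sd = 0,
                           block_sd = 0, gei_sd_water = 0, gei_sd_soil = 0,
                           gei_sd_interaction = 0, crossover_pairs = 0)
  pop <- simulate_factorial_cross_population(cfg, lines_per_cross = 3)
  arch <- list(grain_yield = simulate_trait_architecture(cfg, "grain_yield"))
  plots <- simulate_trial(pop, arch, cfg, blocks = 3)
  d <- plots[plots$trait == "grain_yield", ]
  # replicate plots of a genotype within an environment are identical
  spread <- tapply(d$value, paste(d$genotype, d$water, d$soil), function(v)
    diff(range(v)))
  expect_true(all(spread == 0))
  # genotype means recover the genetic values exactly (up to the env constant)
  gv <- attr(plots, "genetic_values")[, "grain_yield"]
  sub <- d[d$water == "favorable" & d$soil == "sandy_loam", ]
  means <- tapply(sub$value, sub$genotype, mean)[names(gv)]
  expect_equal(as.numeric(means - mean(means)), as.numeric(gv - mean(gv)),
               tolerance = 1e-12)
})

test_that("trial simulator hits the target heritability", {
  # single-seed check on a wide tolerance band, plus a 20-seed average
  # within +/-0.05; GEI SDs are zeroed so that within-environment genetic
  # variance is the genetic variance the h2 target refers to
  recover_h2 <- function(seed) {
    cfg <- simulation_config(seed = seed, n_markers = 150, qtl_count = 50,
                             heritability = c(grain_yield = 0.6),
                             gei_sd_water = 0, gei_sd_soil = 0,
                             gei_sd_interaction = 0, crossover_pairs = 0)
    pop <- simulate_factorial_cross_population(cfg, lines_per_cross = 10)
    arch <- list(grain_yield = simulate_trait_architecture(cfg, "grain_yield"))
    plots <- simulate_trial(pop, arch, cfg, blocks = 4)
    d <- plots[plots$trait == "grain_yield" & plots$water == "favorable" &
                 plots$soil == "sandy_loam", ]
    fit <- stats::aov(value ~ genotype + factor(block), data = d)
    ms <- summary(fit)[[1]][, "Mean Sq"]
    ms_g <- ms[1]
    ms_e <- ms[3]
    var_g <- (ms_g - ms_e) / 4
    var_g / (var_g + ms_e / 4)
  }
  h2_hat <- vapply(1:20, recover_h2, numeric(1))
  expect_gt(h2_hat[1], 0.45)
  expect_lt(h2_hat[1], 0.75)
  expect_lt(abs(mean(h2_hat) - 0.6), 0.05)
})

test_that("implanted crossover pairs are detectable downstream", {
  cfg <- simulation_config(seed = 8, n_markers = 150, crossover_pairs = 2)
  pop <- simulate_factorial_cross_population(cfg, n_parents_a = 2,
                                             n_parents_b = 2,
                                             lines_per_cross = 15)
  arch <- list(grain_yield = simulate_trait_architecture(cfg, "grain_yield"))
  plots <- simulate_trial(pop, arch, cfg, blocks = 4)
  tab <- anova_partitioned(plots, "grain_yield")
  ms_res <- tab$ms[tab$source == "residual"]
  df_res <- tab$df[tab$source == "residual"]
  lsd <- lsd_value(ms_res, df_res, n_per_mean = 4 * 2)
  cm <- genotype_condition_means(plots, "grain_yield", by = "water")
  found <- detect_crossover(cm, lsd)
  pairs <- attr(plots, "crossover_pairs")
  expect_gte(nrow(found), 2)
  key_found <- paste(pmin(found$genotype_1, found$genotype_2),
                     pmax(found$genotype_1, found$genotype_2))
  key_planted <- paste(pmin(pairs$genotype_fav, pairs$genotype_drought),
                       pmax(pairs$genotype_fav, pairs$genotype_drought))
  expect_true(all(key_planted %in% key_found))
})

test_that("GBS noise injection is controlled, seeded and domain-preserving", {
  cfg0 <- simulation_config(seed = 3, n_markers = 100,
                            missing_rate_marker_range = c(0, 0),
                            missing_rate_genotype_range = c(0, 0),
                            het_rate = 0)
  pop <- simulate_factorial_cross_population(cfg0, lines_per_cross = 10)
  expect_identical(add_gbs_noise(pop, cfg0)$dosage, pop$dosage)

  # exactly the 10 designated markers fail the 0.3 marker filter
  noisy <- add_gbs_noise(pop, cfg0, bad_markers = 1:10,
                         bad_marker_rate_range = c(0.4, 0.5))
  stats <- compute_marker_stats(noisy)
  fails <- which(stats$marker$missing_rate >= 0.3)
  expect_identical(fails, 1:10)

  cfg1 <- simulation_config(seed = 3, n_markers = 100, het_rate = 0.05)
  n1 <- add_gbs_noise(pop, cfg1)
  n2 <- add_gbs_noise(pop, cfg1)
  expect_identical(n1$dosage, n2$dosage)
  expect_true(all(n1$dosage %in% c(0, 1, 2) | is.na(n1$dosage)))
  expect_error(
    simulation_config(seed = 1, missing_rate_marker_range = c(0.2, 1)),
    "\\[0,1\\)")
})
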