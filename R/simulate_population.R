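#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator: marker panel size,
#' trait architectures, heritabilities, genotype-by-environment interaction
#' (GEI) magnitudes, trial noise and GBS artefact rates. One integer seed
#' controls all streams; every generator derives a stage-specific sub-stream
#' from it, so identical configurations give identical outputs.
#'
#' Heritability is defined on a genotype-mean basis within one environment:
#' h2 = var_g / (var_g + var_e / r) for r blocks. The trial simulator scales
#' genetic values to meet the target given `plot_error_sd` and the block count.
#' SD-type parameters are expressed in grain-yield units (t/ha); other traits
#' are scaled internally by their characteristic plot-error scale.
#'
#' @param seed integer master seed.
#' @param n_markers number of simulated SNP markers.
#' @param n_chromosomes chromosomes the markers are spread over (white lupin
#'   has 25 chromosome pairs).
#' @param qtl_count number of additive QTL per polygenic trait.
#' @param major_gene_count number of major-effect flowering-time genes.
#' @param heritability named vector of genotype-mean heritabilities in (0,1].
#' @param gei_sd_water,gei_sd_soil,gei_sd_interaction SDs of genotype-specific
#'   sensitivities to water level, soil type and their combination (t/ha).
#' @param crossover_pairs number of genotype pairs implanted with sign-flipped
#'   water sensitivities so that rank-reversing (crossover) GEI is present.
#' @param crossover_delta magnitude (t/ha) of each implanted sensitivity.
#' @param block_sd SD of block-within-environment effects (t/ha).
#' @param plot_error_sd SD of plot residual error (t/ha).
#' @param missing_rate_marker_range,missing_rate_genotype_range ranges from
#'   which per-marker / per-genotype GBS missingness rates are drawn.
#' @param het_rate rate at which homozygous calls are miscalled heterozygous.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_markers = 1500L,
                              n_chromosomes = 25L,
                              qtl_count = 100L,
                              major_gene_count = 2L,
                              heritability = c(grain_yield = 0.6,
                                               straw = 0.6,
                                               flowering = 0.9,
                                               maturity = 0.8,
                                               height = 0.7,
                                               seed_weight = 0.8),
                              gei_sd_water = 0.08,
                              gei_sd_soil = 0.08,
                              gei_sd_interaction = 0.04,
                              crossover_pairs = 2L,
                              crossover_delta = 0.55,
                              block_sd = 0.10,
                              plot_error_sd = 0.35,
                              missing_rate_marker_range = c(0.01, 0.20),
                              missing_rate_genotype_range = c(0.01, 0.10),
                              het_rate = 0.02) {
  .assert_count(seed + 1, "seed")  # allow seed 0
  .assert_count(n_markers, "n_markers")
  .assert_count(n_chromosomes, "n_chromosomes")
  if (qtl_count < 0 || major_gene_count < 0) {
    stop("QTL and major-gene counts must be non-negative")
  }
  if (any(heritability <= 0) || any(heritability > 1)) {
    stop("heritabilities must lie in (0, 1]")
  }
  .assert_fraction(missing_rate_marker_range, "missing_rate_marker_range")
  .assert_fraction(missing_rate_genotype_range, "missing_rate_genotype_range")
  .assert_fraction(het_rate, "het_rate")
  for (s in c(gei_sd_water, gei_sd_soil, gei_sd_interaction, block_sd,
              plot_error_sd, crossover_delta)) {
    if (s < 0) stop("SD parameters must be non-negative")
  }
  structure(list(
    seed = as.integer(seed),
    n_markers = as.integer(n_markers),
    n_chromosomes = as.integer(n_chromosomes),
    qtl_count = as.integer(qtl_count),
    major_gene_count = as.integer(major_gene_count),
    heritability = heritability,
    gei_sd_water = gei_sd_water,
    gei_sd_soil = gei_sd_soil,
    gei_sd_interaction = gei_sd_interaction,
    crossover_pairs = as.integer(crossover_pairs),
    crossover_delta = crossover_delta,
    block_sd = block_sd,
    plot_error_sd = plot_error_sd,
    missing_rate_marker_range = missing_rate_marker_range,
    missing_rate_genotype_range = missing_rate_genotype_range,
    het_rate = het_rate
  ), class = "simulation_config")
}

#' Read/write a simulation configuration as YAML
#'
#' @param config a [simulation_config()].
#' @param path file path.
#' @export
write_simulation_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$heritability <- unlist(x$heritability)
  x$missing_rate_marker_range <- unlist(x$missing_rate_marker_range)
  x$missing_rate_genotype_range <- unlist(x$missing_rate_genotype_range)
  do.call(simulation_config, x)
}

# Marker coordinates: markers spread evenly over chromosomes.
.marker_map <- function(config) {
  p <- config$n_markers
  chrom <- rep(seq_len(config$n_chromosomes), length.out = p)
  chrom <- sort(chrom)
  pos <- unlist(lapply(split(seq_len(p), chrom), seq_along), use.names = FALSE)
  list(chrom = chrom, pos = pos * 100000L)
}

#' Simulate an inbred-line population from a factorial mating design
#'
#' Crosses each of `n_parents_a` parents with each of `n_parents_b` parents
#' and advances `lines_per_cross` lines per cross by single-seed descent for
#' `inbreeding_generations` selfing generations. Founder parents are fully
#' inbred with locus allele frequencies drawn Uniform(0.1, 0.9); loci
#' segregate independently. At loci where the two parents differ, residual
#' heterozygosity after g selfing generations is (1/2)^g.
#'
#' The default 4 x 4 design with 45 lines per cross emulates a breeding-line
#' reference population of ~716 lines from 16 crosses.
#'
#' @param config a [simulation_config()].
#' @param n_parents_a,n_parents_b parents on each side of the factorial.
#' @param lines_per_cross inbred lines derived per cross.
#' @param inbreeding_generations selfing generations after the F1.
#' @return A [genotype_matrix()] with a `cross` attribute (cross label per
#'   line) and a `parents` attribute (founder dosage matrix).
#' @export
simulate_factorial_cross_population <- function(config,
                                                n_parents_a = 4L,
                                                n_parents_b = 4L,
                                                lines_per_cross = 45L,
                                                inbreeding_generations = 5L) {
  .assert_count(n_parents_a, "n_parents_a")
  .assert_count(n_parents_b, "n_parents_b")
  .assert_count(lines_per_cross, "lines_per_cross")
  .assert_count(inbreeding_generations, "inbreeding_generations")
  p <- config$n_markers
  .with_seed(.derive_seed(config$seed, "factorial_cross"), {
    freq <- stats::runif(p, 0.1, 0.9)
    n_par <- n_parents_a + n_parents_b
    # fully inbred founders: dosage 0 or 2
    parents <- matrix(2 * stats::rbinom(n_par * p, 1, rep(freq, each = n_par)),
                      nrow = n_par)
    rownames(parents) <- c(paste0("A", seq_len(n_parents_a)),
                           paste0("B", seq_len(n_parents_b)))
    n_lines <- n_parents_a * n_parents_b * lines_per_cross
    dosage <- matrix(0, n_lines, p)
    cross <- character(n_lines)
    ids <- character(n_lines)
    p_het <- 0.5 ^ inbreeding_generations
    row <- 0L
    for (a in seq_len(n_parents_a)) {
      for (b in seq_len(n_parents_b)) {
        pa <- parents[a, ]
        pb <- parents[n_parents_a + b, ]
        seg <- pa != pb         # segregating loci in this cross
        n_seg <- sum(seg)
        for (l in seq_len(lines_per_cross)) {
          row <- row + 1L
          g <- pa                # fixed loci inherit the shared allele
          if (n_seg > 0) {
            u <- stats::runif(n_seg)
            # SSD endpoint: het with prob (1/2)^g, else fixed 0/2 equally
            g[seg] <- ifelse(u < p_het, 1,
                             ifelse(u < p_het + (1 - p_het) / 2, 0, 2))
          }
          dosage[row, ] <- g
          cross[row] <- sprintf("A%dxB%d", a, b)
          ids[row] <- sprintf("L_A%d_B%d_%02d", a, b, l)
        }
      }
    }
    map <- .marker_map(config)
    out <- genotype_matrix(dosage, genotype_ids = ids,
                           marker_ids = paste0("M", seq_len(p)),
                           chrom = map$chrom, pos = map$pos)
    attr(out, "cross") <- cross
    attr(out, "parents") <- parents
    attr(out, "founder_freq") <- freq
    out
  })
}

#' Simulate a landrace collection of related genotypes
#'
#' Draws accession-level allele frequencies around global frequencies
#' (Balding-Nichols beta model, differentiation `fst`) and then samples
#' `genotypes_per_accession` partially inbred genotypes per accession, so
#' genotypes from the same accession are more similar than genotypes from
#' different accessions. Defaults emulate a 113-accession collection sampled
#' four genotypes deep (452 genotypes).
#'
#' @param config a [simulation_config()].
#' @param n_accessions number of landrace accessions.
#' @param genotypes_per_accession genotypes sampled per accession.
#' @param fst accession differentiation (0, 1).
#' @param selfing_f within-accession inbreeding coefficient; lupin landraces
#'   are predominantly selfing, so heterozygosity is strongly reduced.
#' @return A [genotype_matrix()] with an `accession` attribute.
#' @export
simulate_landrace_collection <- function(config,
                                         n_accessions = 113L,
                                         genotypes_per_accession = 4L,
                                         fst = 0.2,
                                         selfing_f = 0.9) {
  .assert_count(n_accessions, "n_accessions")
  .assert_count(genotypes_per_accession, "genotypes_per_accession")
  .assert_fraction(fst, "fst")
  .assert_fraction(selfing_f, "selfing_f", upper_open = FALSE)
  p <- config$n_markers
  .with_seed(.derive_seed(config$seed, "landrace_collection"), {
    global <- stats::runif(p, 0.1, 0.9)
    shape <- (1 - fst) / max(fst, 1e-8)
    n <- n_accessions * genotypes_per_accession
    dosage <- matrix(0, n, p)
    accession <- rep(paste0("ACC", sprintf("%03d", seq_len(n_accessions))),
                     each = genotypes_per_accession)
    for (a in seq_len(n_accessions)) {
      pf <- stats::rbeta(p, global * shape, (1 - global) * shape)
      rows <- ((a - 1L) * genotypes_per_accession + 1L):(a * genotypes_per_accession)
      for (i in rows) {
        het <- stats::rbinom(p, 1, 2 * pf * (1 - pf) * (1 - selfing_f))
        hom_alt <- stats::rbinom(p, 1, pmin(1, pf^2 + selfing_f * pf * (1 - pf)) /
                                   pmax(1e-12, 1 - 2 * pf * (1 - pf) * (1 - selfing_f)))
        dosage[i, ] <- ifelse(het == 1, 1, 2 * hom_alt)
      }
    }
    ids <- paste0(accession, "_g", rep(seq_len(genotypes_per_accession),
                                       times = n_accessions))
    map <- .marker_map(config)
    out <- genotype_matrix(dosage, genotype_ids = ids,
                           marker_ids = paste0("M", seq_len(p)),
                           chrom = map$chrom, pos = map$pos)
    attr(out, "accession") <- accession
    out
  })
}
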