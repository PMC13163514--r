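# End-to-end proof-of-concept workflow: simulate -> QC -> train -> predict ->
# phenology-constrained selection -> managed-environment validation.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Pipeline configuration
#'
#' One configuration object drives the whole proof-of-concept run. The
#' defaults mirror the emulated breeding programme: a 716-line breeding
#' population from a 4 x 4 factorial mating design (16 crosses x 45 lines,
#' i.e. 720 simulated lines), a 113-accession landrace collection sampled 4
#' genotypes deep (452 genotypes), training sets of 138 / 81 / 140
#' genotypes, GBS QC thresholds 0.3 / 0.5 / 0.3, an m +/- s phenology
#' window, and 2 water x 2 soil environments with 4 complete blocks.
#'
#' @param seed master seed; every stochastic stage derives its own stream.
#' @param sim a [simulation_config()]; defaults to one seeded from `seed`.
#' @param lines_per_cross inbred lines per cross in the breeding population.
#' @param n_accessions,genotypes_per_accession landrace collection shape.
#' @param n_train_bl_drought,n_train_lg_drought,n_train_bl_lime training-set
#'   sizes for the three selection tracks.
#' @param marker_miss_max,genotype_miss_max,het_max QC thresholds.
#' @param half_width_sd phenology window half-width (SD units).
#' @param blocks complete blocks per environment.
#' @param tracks subset of `"bl_drought"`, `"lg_drought"`, `"bl_lime"` to run.
#' @param out_dir optional directory for intermediate artifacts (CSV/JSON);
#'   `NULL` keeps everything in memory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = simulation_config(seed = seed),
                            lines_per_cross = 45L,
                            n_accessions = 113L,
                            genotypes_per_accession = 4L,
                            n_train_bl_drought = 138L,
                            n_train_lg_drought = 81L,
                            n_train_bl_lime = 140L,
                            marker_miss_max = 0.3,
                            genotype_miss_max = 0.5,
                            het_max = 0.3,
                            half_width_sd = 1,
                            blocks = 4L,
                            tracks = c("bl_drought", "lg_drought", "bl_lime"),
                            out_dir = NULL) {
  tracks <- match.arg(tracks, several.ok = TRUE)
  structure(list(seed = as.integer(seed), sim = sim,
                 lines_per_cross = as.integer(lines_per_cross),
                 n_accessions = as.integer(n_accessions),
                 genotypes_per_accession = as.integer(genotypes_per_accession),
                 n_train_bl_drought = as.integer(n_train_bl_drought),
                 n_train_lg_drought = as.integer(n_train_lg_drought),
                 n_train_bl_lime = as.integer(n_train_bl_lime),
                 marker_miss_max = marker_miss_max,
                 genotype_miss_max = genotype_miss_max,
                 het_max = het_max,
                 half_width_sd = half_width_sd,
                 blocks = as.integer(blocks),
                 tracks = tracks, out_dir = out_dir),
            class = "pipeline_config")
}

# genotype means for one trait, optionally restricted to water/soil levels
.genotype_means <- function(plots, trait, water = NULL, soil = NULL) {
  d <- plots[plots$trait == trait, , drop = FALSE]
  if (!is.null(water)) d <- d[d$water %in% water, , drop = FALSE]
  if (!is.null(soil)) d <- d[d$soil %in% soil, , drop = FALSE]
  out <- tapply(d$value, d$genotype, mean)
  stats::setNames(as.numeric(out), names(out))
}

.write_artifact <- function(out_dir, track, name, obj) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(file.path(out_dir, track), recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, track, name)
  if (inherits(obj, "bv_set")) {
    write_bv_csv(obj, path)
  } else if (is.data.frame(obj)) {
    utils::write.csv(obj, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(path)
}

# Fit models on the training ids, predict the candidates, apply the
# phenology window and select the contrasting trio; then confront the
# selection with the simulated trial data under the target condition.
.validate_trio <- function(plots, selected, trait, condition_col, stressed_level,
                           blocks) {
  sub <- plots[plots$genotype %in% selected, , drop = FALSE]
  tab <- anova_partitioned(sub, trait)
  ms_res <- tab$ms[tab$source == "residual"]
  df_res <- tab$df[tab$source == "residual"]
  lsd <- lsd_value(ms_res, df_res, n_per_mean = blocks * 2)
  cond_means <- genotype_condition_means(sub, trait, by = condition_col)
  stress_means <- stats::setNames(cond_means[selected, stressed_level],
                                  names(selected))
  ordering <- stress_means["top"] > stress_means["mid"] &&
    stress_means["mid"] > stress_means["bottom"]
  top_vs_bottom <- stress_means["top"] > stress_means["bottom"]
  crossover <- detect_crossover(cond_means, lsd)
  list(anova = as.data.frame(tab), lsd_condition_mean = lsd,
       stress_means = as.list(stress_means),
       ordering_realized = unname(ordering),
       top_gt_bottom = unname(top_vs_bottom),
       crossover = crossover)
}

.track_bl_drought <- function(cfg) {
  sim <- cfg$sim
  geno_true <- .stage("simulate_population", simulate_factorial_cross_population(
    sim, lines_per_cross = cfg$lines_per_cross))
  arch <- .stage("trait_architecture", list(
    grain_yield = simulate_trait_architecture(sim, "grain_yield"),
    flowering = simulate_trait_architecture(sim, "flowering")))
  plots <- .stage("simulate_trial",
                  simulate_trial(geno_true, arch, sim, blocks = cfg$blocks))
  noisy <- .stage("gbs_noise", add_gbs_noise(geno_true, sim))
  qc <- .stage("qc_filter", filter_genotype_matrix(
    noisy, marker_miss_max = cfg$marker_miss_max,
    genotype_miss_max = cfg$genotype_miss_max, het_max = cfg$het_max))
  geno <- .stage("imputation", impute_missing(qc$geno))
  ids <- genotype_ids(geno)
  n_train <- min(cfg$n_train_bl_drought, length(ids) - 3L)
  train <- .with_seed(.derive_seed(cfg$seed, "train_bl_drought"),
                      sort(sample(ids, n_train)))
  candidates <- setdiff(ids, train)
  y_train <- .genotype_means(plots, "grain_yield", water = "drought")[train]
  fl_train <- .genotype_means(plots, "flowering")[train]
  m_rr <- .stage("fit_rrblup", fit_rrblup(geno[train, ], y_train))
  m_wg <- .stage("fit_wgblup", fit_wgblup(geno[train, ], y_train))
  m_fl <- .stage("fit_flowering", fit_rrblup(geno[train, ], fl_train))
  cand_geno <- geno[candidates, ]
  pred <- .stage("predict", average_predictions(list(
    predict_gebv(m_rr, cand_geno, trait = "grain_yield"),
    predict_gebv(m_wg, cand_geno, trait = "grain_yield"))))
  pred_fl <- predict_gebv(m_fl, cand_geno, trait = "flowering")
  window <- .stage("phenology_window",
                   phenology_window(pred_fl, cfg$half_width_sd))
  sel <- .stage("selection", select_contrasting(pred, window))
  val <- .stage("validation", .validate_trio(
    plots, sel$selected, "grain_yield", "water", "drought", cfg$blocks))
  .write_artifact(cfg$out_dir, "bl_drought", "qc_report.csv", qc$report)
  .write_artifact(cfg$out_dir, "bl_drought", "predicted_yield.csv", pred)
  .write_artifact(cfg$out_dir, "bl_drought", "predicted_flowering.csv", pred_fl)
  .write_artifact(cfg$out_dir, "bl_drought", "anova.csv", val$anova)
  list(
    counts = list(simulated = length(genotype_ids(geno_true)),
                  post_qc = length(ids), training = length(train),
                  candidates = length(candidates),
                  phenology_pass = sum(window)),
    phenology_pass_fraction = mean(window),
    selected = as.list(sel$selected),
    predicted_values = as.list(round(sel$index_values[sel$selected], 6)),
    validation = val
  )
}

.track_lg_drought <- function(cfg) {
  sim <- cfg$sim
  geno_true <- .stage("simulate_population", simulate_landrace_collection(
    sim, n_accessions = cfg$n_accessions,
    genotypes_per_accession = cfg$genotypes_per_accession))
  accession <- attr(geno_true, "accession")
  arch <- .stage("trait_architecture", list(
    grain_yield = simulate_trait_architecture(sim, "grain_yield"),
    flowering = simulate_trait_architecture(sim, "flowering")))
  plots <- .stage("simulate_trial",
                  simulate_trial(geno_true, arch, sim, blocks = cfg$blocks))
  noisy <- .stage("gbs_noise", add_gbs_noise(geno_true, sim))
  qc <- .stage("qc_filter", filter_genotype_matrix(
    noisy, marker_miss_max = cfg$marker_miss_max,
    genotype_miss_max = cfg$genotype_miss_max, het_max = cfg$het_max))
  geno <- .stage("imputation", impute_missing(qc$geno))
  ids <- genotype_ids(geno)
  # accession-level flowering observed in each of the four environments
  fl <- plots[plots$trait == "flowering", ]
  fl$env <- paste(fl$water, fl$soil, sep = "/")
  fl$acc <- accession[match(fl$genotype, genotype_ids(geno_true))]
  acc_by_env <- lapply(split(fl, fl$env), function(d) {
    stats::setNames(as.numeric(tapply(d$value, d$acc, mean)),
                    names(tapply(d$value, d$acc, mean)))
  })
  acc_window <- .stage("phenology_window",
                       multi_environment_window(acc_by_env, cfg$half_width_sd))
  pass_acc <- names(acc_window)[acc_window]
  n_train <- min(cfg$n_train_lg_drought, length(ids) - 3L)
  train <- .with_seed(.derive_seed(cfg$seed, "train_lg_drought"),
                      sort(sample(ids, n_train)))
  candidates <- setdiff(ids, train)
  cand_mask <- stats::setNames(
    accession[match(candidates, genotype_ids(geno_true))] %in% pass_acc,
    candidates)
  y_train <- .genotype_means(plots, "grain_yield", water = "drought")[train]
  m_rr <- .stage("fit_rrblup", fit_rrblup(geno[train, ], y_train))
  pred <- .stage("predict", predict_gebv(m_rr, geno[candidates, ],
                                         trait = "grain_yield"))
  sel <- .stage("selection", select_contrasting(pred, cand_mask))
  val <- .stage("validation", .validate_trio(
    plots, sel$selected, "grain_yield", "water", "drought", cfg$blocks))
  .write_artifact(cfg$out_dir, "lg_drought", "qc_report.csv", qc$report)
  .write_artifact(cfg$out_dir, "lg_drought", "predicted_yield.csv", pred)
  .write_artifact(cfg$out_dir, "lg_drought", "anova.csv", val$anova)
  list(
    counts = list(simulated = length(genotype_ids(geno_true)),
                  post_qc = length(ids),
                  accessions = length(acc_window),
                  accessions_pass = sum(acc_window),
                  training = length(train),
                  candidates = length(candidates),
                  candidates_pass = sum(cand_mask)),
    accession_pass_fraction = mean(acc_window),
    selected = as.list(sel$selected),
    predicted_values = as.list(round(sel$index_values[sel$selected], 6)),
    validation = val
  )
}

.track_bl_lime <- function(cfg) {
  sim <- cfg$sim
  geno_true <- .stage("simulate_population", simulate_factorial_cross_population(
    sim, lines_per_cross = cfg$lines_per_cross))
  arch <- .stage("trait_architecture", list(
    grain_yield = simulate_trait_architecture(sim, "grain_yield"),
    flowering = simulate_trait_architecture(sim, "flowering")))
  plots <- .stage("simulate_trial",
                  simulate_trial(geno_true, arch, sim, blocks = cfg$blocks))
  noisy <- .stage("gbs_noise", add_gbs_noise(geno_true, sim))
  qc <- .stage("qc_filter", filter_genotype_matrix(
    noisy, marker_miss_max = cfg$marker_miss_max,
    genotype_miss_max = cfg$genotype_miss_max, het_max = cfg$het_max))
  geno <- .stage("imputation", impute_missing(qc$geno))
  ids <- genotype_ids(geno)
  n_train <- min(cfg$n_train_bl_lime, length(ids) - 3L)
  train <- .with_seed(.derive_seed(cfg$seed, "train_bl_lime"),
                      sort(sample(ids, n_train)))
  candidates <- setdiff(ids, train)
  # main-site phenotypes: yield in the calcareous (silty-clay) soil and a
  # visual lime-susceptibility score negatively related to soil adaptation
  y_calc <- .genotype_means(plots, "grain_yield", soil = "silty_clay")
  sens <- attr(plots, "sensitivities")$grain_yield
  susc_all <- .with_seed(.derive_seed(cfg$seed, "susceptibility"), {
    s <- sens$soil[match(ids, sens$genotype)]
    z <- if (stats::sd(s) > 0) (s - mean(s)) / stats::sd(s) else s * 0
    # silty_clay enters the plot model with c_s = -1: positive soil
    # sensitivity means worse calcareous performance, i.e. susceptibility
    stats::setNames(5 + z + stats::rnorm(length(ids), 0, 0.7), ids)
  })
  ens_all <- .with_seed(.derive_seed(cfg$seed, "ens_site"), {
    z <- (y_calc[ids] - mean(y_calc[ids])) / stats::sd(y_calc[ids])
    stats::setNames(3.5 + 0.35 * z + stats::rnorm(length(ids), 0, 0.45), ids)
  })
  fl_train <- .genotype_means(plots, "flowering")[train]
  m_y <- .stage("fit_rrblup", fit_rrblup(geno[train, ], y_calc[train]))
  m_su <- .stage("fit_susceptibility", fit_rrblup(geno[train, ], susc_all[train]))
  m_ens <- .stage("fit_ens", fit_rrblup(geno[train, ], ens_all[train]))
  m_fl <- .stage("fit_flowering", fit_rrblup(geno[train, ], fl_train))
  cand_geno <- geno[candidates, ]
  pred_y <- predict_gebv(m_y, cand_geno, trait = "grain_yield")
  pred_su <- predict_gebv(m_su, cand_geno, trait = "susceptibility")
  pred_ens <- predict_gebv(m_ens, cand_geno, trait = "grain_yield_ens")
  pred_fl <- predict_gebv(m_fl, cand_geno, trait = "flowering")
  index <- .stage("lime_index", lime_adaptation_index(pred_y, pred_su))
  window <- .stage("phenology_window",
                   phenology_window(pred_fl, cfg$half_width_sd))
  masks <- list(top = quartile_mask(pred_ens, "top_quartile"),
                mid = quartile_mask(pred_ens, "middle_quartiles"),
                bottom = quartile_mask(pred_ens, "below_average"))
  sel <- .stage("selection", select_contrasting(index, window, masks))
  val <- .stage("validation", .validate_trio(
    plots, sel$selected, "grain_yield", "soil", "silty_clay", cfg$blocks))
  .write_artifact(cfg$out_dir, "bl_lime", "qc_report.csv", qc$report)
  .write_artifact(cfg$out_dir, "bl_lime", "lime_index.csv", index)
  .write_artifact(cfg$out_dir, "bl_lime", "anova.csv", val$anova)
  list(
    counts = list(simulated = length(genotype_ids(geno_true)),
                  post_qc = length(ids), training = length(train),
                  candidates = length(candidates),
                  phenology_pass = sum(window)),
    phenology_pass_fraction = mean(window),
    selected = as.list(sel$selected),
    index_values = as.list(round(sel$index_values[sel$selected], 6)),
    validation = val
  )
}

#' Run the full genomic-selection proof-of-concept pipeline
#'
#' Executes up to three selection tracks on synthetic populations:
#' breeding lines selected for drought adaptation (rrBLUP + weighted-GBLUP
#' averaged predictions, phenology window on predicted flowering), landrace
#' genotypes selected for drought adaptation (rrBLUP, phenology window on
#' observed accession flowering enforced across all four environments), and
#' breeding lines selected for adaptation to moderately calcareous soil
#' (standardized yield + inverted susceptibility index, secondary-site
#' quartile constraints). Each track ends in a simulated 2 water x 2 soil
#' randomized-complete-block validation and reports whether the predicted
#' top > mid > bottom ordering was realized under the target stress.
#'
#' @param config a [pipeline_config()].
#' @return A run report (nested list): per-track candidate counts after each
#'   constraint, selected genotypes, predicted values, validation ANOVA,
#'   realized stress means, ordering flags and detected crossover pairs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  runners <- list(bl_drought = .track_bl_drought,
                  lg_drought = .track_lg_drought,
                  bl_lime = .track_bl_lime)
  report <- list(seed = config$seed, tracks = list())
  for (tr in config$tracks) {
    report$tracks[[tr]] <- runners[[tr]](config)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' Load a genotype matrix from delimited, VCF or HapMap-like files
#'
#' Delimited matrices are genotypes x markers with a leading id column (as
#' written by [write_genotype_matrix()]). VCF files are read through the
#' `vcfR` package and unphased/phased diploid GT fields are decoded to
#' alternate-allele dosages. HapMap-like files carry 11 metadata columns
#' followed by two-letter genotype calls decoded against the `alleles`
#' column. Calls that cannot be decoded become missing, with a message
#' reporting the count.
#'
#' @param path input file.
#' @param format `"matrix"`, `"vcf"` or `"hapmap"`.
#' @return A [genotype_matrix()].
#' @export
load_genotypes <- function(path, format = c("matrix", "vcf", "hapmap")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file.size(path) == 0) stop(sprintf("empty input file: %s", path))
  switch(format,
    matrix = read_genotype_matrix(path),
    vcf = {
      v <- vcfR::read.vcfR(path, verbose = FALSE)
      gt <- vcfR::extract.gt(v, element = "GT")
      decode <- function(x) {
        alleles <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
        vapply(alleles, function(a) {
          if (length(a) != 2 || any(a == ".")) return(NA_real_)
          suppressWarnings(s <- sum(as.numeric(a != "0")))
          s
        }, numeric(1))
      }
      dosage <- t(apply(gt, 2, decode))
      if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = ncol(gt))
      rownames(dosage) <- colnames(gt)
      colnames(dosage) <- rownames(gt)
      n_bad <- sum(is.na(dosage) & !is.na(t(gt)) & t(gt) != "./." & t(gt) != ".|.")
      if (n_bad > 0) message(sprintf("%d undecodable GT call(s) set to missing", n_bad))
      genotype_matrix(dosage,
                      chrom = as.character(v@fix[, "CHROM"]),
                      pos = as.numeric(v@fix[, "POS"]))
    },
    hapmap = {
      df <- utils::read.delim(path, check.names = FALSE,
                              colClasses = "character")
      if (ncol(df) <= 11) stop("HapMap file has no genotype columns")
      alleles <- strsplit(df$alleles, "/", fixed = TRUE)
      gt_cols <- 12:ncol(df)
      n_bad <- 0L
      dosage <- vapply(gt_cols, function(ci) {
        calls <- toupper(df[[ci]])
        vapply(seq_along(calls), function(k) {
          al <- alleles[[k]]
          cc <- strsplit(calls[k], "")[[1]]
          if (length(cc) != 2 || length(al) != 2 || !all(cc %in% al)) {
            return(NA_real_)
          }
          sum(cc == al[2])
        }, numeric(1))
      }, numeric(nrow(df)))
      dosage <- t(dosage)
      rownames(dosage) <- names(df)[gt_cols]
      colnames(dosage) <- df[[1]]
      n_bad <- sum(is.na(dosage) & !(t(df[, gt_cols]) %in% c("NN", "--")))
      if (n_bad > 0) message(sprintf("%d undecodable call(s) set to missing", n_bad))
      genotype_matrix(dosage, chrom = df$chrom, pos = as.numeric(df$pos))
    })
}

#' Load plot-level phenotypes from tidy CSV
#'
#' Expects columns `genotype`, `water`, `soil`, `block`, `trait`, `value`
#' with water in `drought`/`favorable` and soil in
#' `sandy_loam`/`silty_clay`.
#'
#' @param path CSV file.
#' @return A validated long-format `data.frame`.
#' @export
load_phenotypes <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "water", "soil", "block", "trait", "value")
  absent <- setdiff(need, names(d))
  if (length(absent)) {
    stop("phenotype file lacks column(s): ", paste(absent, collapse = ", "))
  }
  bad_w <- which(!d$water %in% WATER_LEVELS)
  if (length(bad_w)) {
    stop(sprintf("unknown water level '%s' in row %d", d$water[bad_w[1]],
                 bad_w[1]))
  }
  bad_s <- which(!d$soil %in% SOIL_TYPES)
  if (length(bad_s)) {
    stop(sprintf("unknown soil type '%s' in row %d", d$soil[bad_s[1]],
                 bad_s[1]))
  }
  d$block <- as.integer(d$block)
  d$value <- as.numeric(d$value)
  d[, need]
}
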