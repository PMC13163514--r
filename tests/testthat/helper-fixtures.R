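# Shared in-code fixtures for the test suite.

# tiny deterministic dosage matrix with known structure
tiny_geno <- function() {
  m <- rbind(
    G1 = c(0, 2, 0, 1, 2),
    G2 = c(0, 2, 0, 1, 2),
    G3 = c(2, 0, 0, 1, 0),
    G4 = c(2, 0, 2, 0, 0)
  )
  colnames(m) <- paste0("M", 1:5)
  genotype_matrix(m)
}

# balanced plot data with fully controlled effects: one value per
# genotype x water x soil x block cell
manual_plots <- function(g_eff, water_eff = c(drought = 0, favorable = 0),
                         soil_eff = c(sandy_loam = 0, silty_clay = 0),
                         ws_eff = 0, gw_eff = NULL, blocks = 2,
                         block_eff = NULL, noise_sd = 0, trait = "grain_yield",
                         mu = 4, seed = 1) {
  ids <- names(g_eff)
  d <- expand.grid(genotype = ids, water = c("drought", "favorable"),
                   soil = c("sandy_loam", "silty_clay"),
                   block = seq_len(blocks), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  cw <- ifelse(d$water == "drought", -1, 1)
  cs <- ifelse(d$soil == "sandy_loam", 1, -1)
  v <- mu + g_eff[d$genotype] + water_eff[d$water] + soil_eff[d$soil] +
    ws_eff * cw * cs
  if (!is.null(gw_eff)) v <- v + gw_eff[d$genotype] * cw
  if (!is.null(block_eff)) {
    env <- paste(d$water, d$soil)
    v <- v + block_eff[paste(env, d$block)]
  }
  if (noise_sd > 0) {
    v <- v + withr::with_seed(seed, rnorm(nrow(d), 0, noise_sd))
  }
  data.frame(d, trait = trait, value = as.numeric(v),
             stringsAsFactors = FALSE)
}

# quick additive phenotype on a simulated population
additive_phenotype <- function(geno, arch, h2 = 0.6, seed = 1) {
  gv <- as.numeric(geno$dosage %*% arch$effects)
  gv <- (gv - mean(gv)) / stats::sd(gv)
  withr::with_seed(seed, {
    stats::setNames(gv + rnorm(length(gv), 0, sqrt((1 - h2) / h2)),
                    rownames(geno$dosage))
  })
}

extdata <- function(name) {
  path <- system.file("extdata", name, package = "lupings")
  if (!nzchar(path)) path <- file.path("../../inst/extdata", name)
  path
}
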