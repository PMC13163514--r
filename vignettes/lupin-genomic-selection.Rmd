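---
title: "Genomic selection for white lupin stress adaptation: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection for white lupin stress adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lupings)
```

## The problem

White lupin (*Lupinus albus*) is a high-protein grain legume whose yield
collapses under terminal drought and in even moderately calcareous soils
(active lime above roughly 1%). Field selection for either adaptation is slow
and confounded: drought incidence is erratic and soil lime is spatially
heterogeneous. Genomic selection (GS) replaces repeated phenotyping with a
model trained once on a genotyped and phenotyped reference population: marker
effects estimated on the training set predict breeding values (GEBVs) for any
genotyped candidate.

`lupings` implements the full chain that such a programme needs:

1. **genotype QC** — GBS dosage matrices filtered for monomorphic markers,
   marker/genotype missingness and excess heterozygosity, then completed with
   a deterministic k-nearest-genotype imputer;
2. **genomic prediction** — rrBLUP and (weighted) GBLUP with REML-estimated
   shrinkage, cross-validated predictive ability, and the phenology-adjusted
   yield statistic;
3. **selection** — phenology windows, multi-model averaging, the standardized
   lime-adaptation index, secondary-site quartile constraints, and the choice
   of predicted top-, mid- and bottom-performing genotypes;
4. **trial analysis** — 2 water x 2 soil factorial ANOVA with
   block-within-environment error terms, LSD mean separation, crossover GEI
   detection and water-budget accounting;
5. **a synthetic-data generator** that reproduces the statistical structure
   of the breeding populations and managed-environment trials the analysis
   assumes, so every stage is testable without field data.

## The prediction model

All prediction rests on the single-trait mixed model

$$y = \mathbf{1}\mu + W u + e, \qquad
  u \sim N(0, \sigma_u^2 I), \quad e \sim N(0, \sigma_e^2 I),$$

where $W$ is the dosage matrix centred at twice the training allele
frequencies, $u$ the vector of marker effects and
$\lambda = \sigma_e^2/\sigma_u^2$ the shrinkage ratio. $\lambda$ is estimated
by restricted maximum likelihood through the eigendecomposition of $WW'$:
because the centred $W$ has exactly mean-zero columns, the intercept
projection is already absorbed and the REML profile likelihood is a
one-dimensional function of $\lambda$ evaluated on the spectrum
(the EMMA construction). Effects are then
$u = W'(WW' + \lambda I)^{-1}(y - \mu\mathbf{1})$ and predictions for new
genotypes are $\hat g = \mu + W_{new} u$ with $W_{new}$ centred at the
*training* frequencies.

GBLUP is the equivalent kernel formulation, $g \sim N(0, \sigma_g^2 K)$ with
$K = W D W'$ and $D$ a diagonal matrix of marker weights. `fit_wgblup()`
derives the weights from an initial rrBLUP fit as
$d_k = \hat u_k^2 / \overline{\hat u^2}$ (weighted GBLUP); with unit weights
the GEBVs coincide with rrBLUP to numerical precision, a property the test
suite asserts at $10^{-6}$ relative tolerance. The exported `make_grm()`
applies the VanRaden normalisation
$G = W D W' / (2\sum_k d_k p_k(1-p_k))$, which keeps the expected diagonal
near one; the normalisation only rescales the variance component, so the
mixed-model solve inside `fit_wgblup()` uses the unnormalised kernel.

Predictive ability is the Pearson correlation between pooled held-out
predictions and observations in seeded k-fold cross-validation
(`cross_validate()`). Pooled-r cross-validation carries a small negative bias
under the null — held-out fold means anti-correlate with their training
means — which shrinks with fold size; the test suite demonstrates calibration
at fold size 20. `adjusted_yield()` computes the residual of genotype yield
regressed on onset of flowering: a phenology-independent drought-resistance
measure whose residuals are exactly orthogonal to flowering.

## Selection logic

Drought adaptation must not be confused with drought *escape* through very
early flowering, which in autumn-sown Mediterranean environments trades
drought exposure for winter-kill risk. Selection is therefore restricted to a
phenology window: genotypes whose (predicted or observed) onset of flowering
lies within $m \pm s$ of the candidate population (inclusive bounds; on
Normal data the window retains $2\Phi(1)-1 \approx 68.3\%$). For landrace
material the window is applied to accession-level flowering observed in each
of four evaluation environments, and a genotype passes only if its source
accession passes everywhere.

Within the window, `select_contrasting()` picks the genotype with the highest
predicted value (top), the lowest (bottom) and the one closest to the mean of
the candidates' predictions (mid); ties break towards the lexicographically
smallest genotype id so that the decision is deterministic. For adaptation to
calcareous soil the primary index standardizes predicted yield and a
predicted visual lime-susceptibility score to zero mean and unit SD, inverts
the susceptibility sign and averages the two; candidates must additionally
satisfy quartile rules on a secondary site's predicted yield (top role: at or
above the 75th percentile; bottom: below the average; mid: within the
inter-quartile range). Percentiles use linear interpolation between order
statistics, "top quartile" is inclusive at the boundary, and "below average"
is strict — these conventions are pinned so that boundary genotypes are
handled reproducibly.

An open choice is whether the "mid" reference mean is computed over the
phenology-admissible candidates or over all genotypes; candidates-only is the
default (`mid_reference = "candidates"`), with the alternative exposed as an
option.

## Trial analysis

The validation design is a factorial of two water treatments (moderate
terminal drought; moisture-favorable) and two soil types (sandy-loam,
non-calcareous; silty-clay, moderately calcareous), each environment laid out
as a randomized complete block design with four replications.
`anova_partitioned()` computes the balanced-design decomposition in which the
environment variation and its interaction with genotypes are partitioned into
water amount, soil type and water x soil sources. Error terms follow the
design: water, soil and water x soil are tested against the
block-within-environment mean square on $4(r-1)$ df; genotype and all
genotype-involving interactions are tested against the residual. Sums of
squares are obtained from the sequential decomposition of a balanced
orthogonal layout (computed via `aov()`, with the error-term mapping, F and p
assembled explicitly); the test suite verifies every SS against an
independent projection-based decomposition and checks that each F test holds
its size within Monte-Carlo error under a planted null.

LSD mean separation uses
$t_{1-\alpha/2,\,df}\sqrt{2\,\mathrm{MS}_{err}/n}$ with $n$ the number of
plots per mean (8 for genotype means averaged over two soils at $r = 4$; 4
for single-condition cells). Letter groups come from a descending-mean sweep;
a difference of exactly one LSD is significant. `detect_crossover()` reports
genotype pairs whose ranking reverses between two conditions with both
differences at or beyond the LSD — the signature of crossover
genotype-by-environment interaction that makes specific adaptation to drought
worth selecting for. `water_reduction_pct()` and `stress_reduction_pct()`
implement the water-budget and environment-mean bookkeeping
(`round(100*(1 - stressed/favorable))`, reported as whole percent).

On the packaged environment-mean table the reductions are 19% (grain yield,
drought), 23% (grain yield, calcareous soil), 29% and 27% (straw); one
water-budget row prints 64% where the budget formula applied to its own
water amounts yields 64.5 -> 65%, a one-unit rounding inconsistency in the
source table that the package reproduces as computed, not as printed.
Printed harvest-index environment means are treated as means of plot-level
ratios; the ratio-of-means alternative differs by up to 0.01 and the
discrepancy is documented rather than resolved.

## What the simulator emulates — and what it does not

`simulation_config()` defaults encode the conditions of the breeding programme and validation experiment the package models:

* a breeding-line population of 16 families from a 4 x 4 factorial mating
  design, 45 lines per cross (720 lines), advanced to F6 by single-seed
  descent (residual heterozygosity $(1/2)^5$ at segregating loci);
* a landrace collection of 113 accessions sampled four genotypes deep
  (452 genotypes), with accession-level allele frequencies drawn from a
  Balding–Nichols model ($F_{st} = 0.2$) and strong selfing ($F = 0.9$);
* training sets of 138 (lines, drought), 81 (landraces, drought) and 140
  (lines, calcareous soil) genotypes;
* 2 water x 2 soil environments with 4 complete blocks, plot values from
  `cell_mean + g + GEI + block(env) + error`;
* GBS artefacts: per-marker and per-genotype missingness and heterozygous
  miscalls, with hooks to push designated markers/genotypes over the QC
  thresholds (0.3 / 0.5 / 0.3) so the filters are exercised.

Values the study does not state are simulator parameters chosen once for
realism, not estimates of the real populations: 1500 markers over 25
chromosomes (desk-scale; the real filtered panels are ~33k–41k SNPs), 100
QTL per polygenic trait, two major flowering genes carrying at least half the
flowering genetic variance, genotype-mean heritabilities of 0.6 (yields) to
0.9 (flowering), plot error SD 0.35 t/ha for yield, block SD 0.10 t/ha, and
GEI sensitivity SDs of 0.08/0.08/0.04 t/ha. Environment cell means and
per-trait error scales are calibrated to the packaged environment-mean table
and its LSDs (grand mean yield ≈ 3.5 t/ha), so simulated output is on the
scale a lupin agronomist expects. Heritability is defined on genotype means
within one environment, $h^2 = \sigma_g^2/(\sigma_g^2 + \sigma_e^2/r)$; GEI
variance adds to the realized within-environment genetic variance, which is
why heritability-recovery checks zero the GEI SDs.

Crossover GEI is implanted explicitly: `crossover_pairs` pairs of genotypes
receive equal genetic values and opposite water sensitivities
(±`crossover_delta`, default 0.55 t/ha), guaranteeing rank reversals beyond
the trial LSD that `detect_crossover()` must find.

The simulator deliberately omits linkage disequilibrium (loci are
independent), dominance, epistasis and sequence-level read noise. Passing
tests therefore demonstrate that the statistical machinery is correct and
that the selection logic recovers planted signal under the stated noise
model — they do not certify predictive-ability levels on real GBS data,
where LD structure, allele-frequency spectra and GEI are richer.

## Numerical choices

* REML optimizes the profile likelihood over $\log\lambda \in
  [\log 10^{-8}, \log 10^{8}]$ with `optimize()` at tolerance $10^{-10}$;
  degenerate inputs (constant phenotype) short-circuit to zero effects.
* Equivalence checks (rrBLUP vs unit-weight GBLUP, filtering idempotence,
  ANOVA SS additivity) are asserted at $10^{-6}$ relative or tighter.
* Imputation ties resolve towards the smaller dosage; neighbour similarity
  is the fraction of identical calls among mutually observed markers, and a
  marker with no informative neighbour falls back to the marker mode.
* QC threshold semantics are strict `<` as printed ("missing rate < 0.3"),
  so an item exactly at a threshold is removed; marker-level filters run
  before the genotype-level filter, and genotype missingness is recomputed
  on the retained markers (the order matters for borderline items and is
  fixed for reproducibility).
* One master seed drives every stage through derived sub-streams
  (`.derive_seed`), making whole-pipeline runs byte-identical under a fixed
  configuration while keeping stages independently reproducible.

## Problem sizes used in the tests and acceptance runs

Test populations range from 48 to 720 lines with 60–800 markers — large
enough for the statistical properties to hold (heritability recovery within
±0.05 over 20 seeds at n ≥ 150; type-I error of every partitioned-ANOVA F
test within 3 binomial SE of 0.05 over 500 null datasets; predicted-top vs
predicted-bottom separation under simulated drought in ≥ 90% of 20 seeded
pipeline runs at $h^2 = 0.6$ and 150 training lines). The acceptance script
runs the full study-sized population (720 lines) with an 800-marker panel
for cross-validation and 368-line populations with 500 markers for the
20 replicate selection runs; these sizes were chosen as the package's
desk-scale defaults.

## Known limitations

* The ANOVA supports balanced designs only; unbalanced or mixed-model REML
  analyses are out of scope.
* The deterministic k-NN imputer replaces random-forest imputation by
  design; it is reproducible and accurate on structured populations but does
  not model marker-marker interactions.
* Raw-scale averaging of rrBLUP and WGBLUP predictions is implemented; if
  the two models were standardized before averaging the ranking could differ
  for borderline candidates.
* Cross-validated predictive abilities on simulated data depend on the
  simulated genetic architecture and are not estimates of any real
  population's predictive ability.
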