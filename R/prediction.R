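# Genomic prediction: rrBLUP / GBLUP / weighted GBLUP, cross-validation,
# and the phenology-adjusted yield statistic.

#' Breeding-value set
#'
#' A named vector of per-genotype (predicted or observed) values for one
#' trait together with the population mean `m` and sample standard deviation
#' `s` (n - 1 denominator) that selection windows are expressed in.
#'
#' @param values named numeric vector (names = genotype ids).
#' @param trait trait name.
#' @return An object of class `bv_set` with elements `trait`, `values`,
#'   `m`, `s`.
#' @export
bv_set <- function(values, trait = "trait") {
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    stop("values must carry unique genotype names")
  }
  values <- stats::setNames(as.numeric(values), names(values))
  structure(list(trait = trait, values = values,
                 m = mean(values), s = stats::sd(values)),
            class = "bv_set")
}

#' @export
print.bv_set <- function(x, ...) {
  cat(sprintf("bv_set '%s': %d genotypes, m = %.4g, s = %.4g\n",
              x$trait, length(x$values), x$m, x$s))
  invisible(x)
}

#' @export
as.data.frame.bv_set <- function(x, ...) {
  data.frame(genotype = names(x$values), trait = x$trait, value = x$values,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a breeding-value set as CSV
#'
#' @param bv a [bv_set()].
#' @param path file path.
#' @export
write_bv_csv <- function(bv, path) {
  utils::write.csv(as.data.frame(bv), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Centered marker matrix: dosages minus twice the training allele frequency.
# Centering at the observed mean dosage makes the columns exactly mean-zero,
# so the GLS intercept reduces to the phenotype mean.
.center_dosage <- function(dosage, freq = NULL) {
  if (is.null(freq)) freq <- colMeans(dosage) / 2
  sweep(dosage, 2, 2 * freq)
}

# Spectral REML for y = 1*mu + g + e with Var(g) = s2u * K, Var(e) = s2e * I.
# K must satisfy K %*% 1 = 0 (holds for any column-centered W W' construction),
# so the n - 1 non-null eigenpairs of K are the eigenpairs of the
# intercept-projected problem. Returns the REML variance ratio
# delta = s2e / s2u, the GLS intercept and the random-effect solve
# alpha = (K + delta I)^{-1} (y - mu).
.spectral_reml <- function(K, y, lambda = NULL) {
  n <- length(y)
  eg <- eigen(K, symmetric = TRUE)
  theta <- pmax(eg$values[seq_len(n - 1L)], 0)
  U <- eg$vectors[, seq_len(n - 1L), drop = FALSE]
  eta2 <- as.numeric(crossprod(U, y))^2
  if (is.null(lambda)) {
    nll <- function(log_delta) {
      d <- exp(log_delta)
      (n - 1) * log(sum(eta2 / (theta + d))) + sum(log(theta + d))
    }
    opt <- stats::optimize(nll, interval = log(c(1e-8, 1e8)), tol = 1e-10)
    lambda <- exp(opt$minimum)
  }
  H <- K + diag(lambda, n)
  h1 <- solve(H, rep(1, n))
  mu <- sum(h1 * y) / sum(h1)
  alpha <- solve(H, y - mu)
  s2u <- sum(eta2 / (theta + lambda)) / (n - 1)
  list(lambda = lambda, mu = mu, alpha = alpha, s2u = s2u,
       s2e = lambda * s2u)
}

.check_alignment <- function(geno, pheno) {
  if (is.null(names(pheno))) {
    if (length(pheno) != nrow(geno$dosage)) {
      stop("phenotype vector length does not match genotype count")
    }
    names(pheno) <- genotype_ids(geno)
  }
  missing_ids <- setdiff(names(pheno), genotype_ids(geno))
  if (length(missing_ids)) {
    stop("phenotyped genotypes absent from the dosage matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  pheno
}

.new_gs_model <- function(method, intercept, effects, lambda, freq,
                          marker_idv, weights = NULL, fitted = NULL) {
  structure(list(method = method, intercept = intercept,
                 marker_effects = stats::setNames(as.numeric(effects), marker_idv),
                 lambda = lambda, marker_ids = marker_idv,
                 freq = stats::setNames(freq, marker_idv),
                 marker_weights = if (is.null(weights)) NULL else
                   stats::setNames(weights, marker_idv),
                 fitted = fitted),
            class = "gs_model")
}

#' @export
print.gs_model <- function(x, ...) {
  cat(sprintf("gs_model (%s): %d markers, intercept = %.4g, lambda = %.4g\n",
              x$method, length(x$marker_effects), x$intercept, x$lambda))
  invisible(x)
}

#' Fit a ridge-regression BLUP (rrBLUP) genomic prediction model
#'
#' Solves the single-trait mixed model `y = 1*mu + W u + e` with marker
#' effects `u ~ N(0, s2u I)`, where `W` is the allele-frequency-centred
#' dosage matrix. The shrinkage ratio `lambda = s2e / s2u` is estimated by
#' restricted maximum likelihood through the eigendecomposition of `W W'`
#' (closed-form profile likelihood in one variance ratio), and the marker
#' effects are recovered as `u = W' (W W' + lambda I)^{-1} (y - mu)`.
#'
#' @param geno a complete (no missing calls) [genotype_matrix()].
#' @param pheno named numeric vector of genotype-mean phenotypes; names must
#'   match genotype ids (unnamed vectors are matched positionally).
#' @param lambda optional fixed shrinkage ratio; `NULL` (default) estimates
#'   it by REML.
#' @return A `gs_model` with the intercept, per-marker effects, `lambda`,
#'   and the training allele frequencies used for centring.
#' @export
fit_rrblup <- function(geno, pheno, lambda = NULL) {
  pheno <- .check_alignment(geno, pheno)
  X <- geno$dosage[names(pheno), , drop = FALSE]
  if (anyNA(X)) stop("dosage matrix contains missing calls; impute first")
  n <- length(pheno)
  if (n < 3) stop("at least 3 phenotyped genotypes are required")
  freq <- colMeans(X) / 2
  if (stats::sd(pheno) == 0) {
    return(.new_gs_model("rrblup", pheno[[1]], numeric(ncol(X)), Inf, freq,
                         marker_ids(geno),
                         fitted = stats::setNames(rep(pheno[[1]], n),
                                                  names(pheno))))
  }
  W <- .center_dosage(X, freq)
  K <- tcrossprod(W)
  fit <- .spectral_reml(K, as.numeric(pheno), lambda = lambda)
  u <- as.numeric(crossprod(W, fit$alpha))
  fitted <- stats::setNames(fit$mu + as.numeric(W %*% u), names(pheno))
  .new_gs_model("rrblup", fit$mu, u, fit$lambda, freq, marker_ids(geno),
                fitted = fitted)
}

#' Genomic relationship matrix (VanRaden construction)
#'
#' `G = W D W' / (2 * sum_k d_k p_k (1 - p_k))` with `W` the
#' allele-frequency-centred dosage matrix and `D = diag(weights)` (identity
#' when `weights` is `NULL`). The weighted normalisation keeps the expected
#' diagonal near 1 for unstructured populations whatever the weights.
#'
#' @param geno a complete [genotype_matrix()].
#' @param weights optional non-negative per-marker weights.
#' @return A symmetric genotype x genotype matrix.
#' @export
make_grm <- function(geno, weights = NULL) {
  X <- geno$dosage
  if (nrow(X) < 2) stop("at least 2 genotypes are required")
  if (anyNA(X)) stop("dosage matrix contains missing calls; impute first")
  p <- ncol(X)
  if (is.null(weights)) weights <- rep(1, p)
  if (length(weights) != p || any(weights < 0)) {
    stop("weights must be non-negative, one per marker")
  }
  freq <- colMeans(X) / 2
  denom <- 2 * sum(weights * freq * (1 - freq))
  if (denom == 0) stop("all markers are monomorphic; GRM undefined")
  W <- .center_dosage(X, freq)
  G <- tcrossprod(sweep(W, 2, weights, `*`), W) / denom
  dimnames(G) <- list(genotype_ids(geno), genotype_ids(geno))
  G
}

#' Fit a (weighted) GBLUP genomic prediction model
#'
#' GBLUP formulation of genomic prediction: `y = 1*mu + g + e` with
#' `g ~ N(0, s2g G)` where `G` is the (weighted) genomic relationship matrix
#' from [make_grm()]. By default the marker weights are
#' `d_k = u_k^2 / mean(u^2)` from an initial rrBLUP fit, so markers with
#' large estimated effects contribute more relationship information
#' (weighted GBLUP). With unit weights the genotype breeding values are
#' numerically equivalent to rrBLUP. Marker effects are back-solved as
#' `u = D W' alpha / c` so the model can predict unphenotyped genotypes.
#'
#' @param geno a complete [genotype_matrix()].
#' @param pheno named numeric phenotype vector (as in [fit_rrblup()]).
#' @param base_model optional rrBLUP `gs_model` supplying the weights;
#'   fitted internally when absent.
#' @param weights optional explicit marker weights overriding `base_model`
#'   (unit weights give plain GBLUP).
#' @return A `gs_model` (method `"wgblup"`) with back-solved marker effects
#'   and the marker weights used.
#' @export
fit_wgblup <- function(geno, pheno, base_model = NULL, weights = NULL) {
  pheno <- .check_alignment(geno, pheno)
  X <- geno$dosage[names(pheno), , drop = FALSE]
  if (anyNA(X)) stop("dosage matrix contains missing calls; impute first")
  if (length(pheno) < 3) stop("at least 3 phenotyped genotypes are required")
  sub <- geno[match(names(pheno), genotype_ids(geno)), ]
  if (is.null(weights)) {
    if (is.null(base_model)) base_model <- fit_rrblup(sub, pheno)
    u0 <- base_model$marker_effects
    msq <- mean(u0^2)
    weights <- if (msq == 0) rep(1, length(u0)) else u0^2 / msq
  }
  freq <- colMeans(X) / 2
  if (stats::sd(pheno) == 0) {
    return(.new_gs_model("wgblup", pheno[[1]], numeric(ncol(X)), Inf, freq,
                         marker_ids(geno), weights = weights,
                         fitted = stats::setNames(rep(pheno[[1]], length(pheno)),
                                                  names(pheno))))
  }
  # weighted relationship kernel K = W D W'; the VanRaden scaling of
  # make_grm() only rescales the variance component, not the GEBVs, so the
  # unnormalized kernel is used for the mixed-model solve
  W <- .center_dosage(X, freq)
  K <- tcrossprod(sweep(W, 2, weights, `*`), W)
  if (all(K == 0)) stop("all markers are monomorphic; GBLUP undefined")
  fit <- .spectral_reml(K, as.numeric(pheno))
  u <- as.numeric(crossprod(W, fit$alpha) * weights)
  fitted <- stats::setNames(fit$mu + as.numeric(W %*% u), names(pheno))
  .new_gs_model("wgblup", fit$mu, u, fit$lambda, freq, marker_ids(geno),
                weights = weights, fitted = fitted)
}

#' Predict genomic breeding values for new genotypes
#'
#' `GEBV = mu + W_new u`, where `W_new` centres the new dosages at the
#' TRAINING allele frequencies stored in the model. Every model marker must
#' be present in the new matrix.
#'
#' @param model a `gs_model` from [fit_rrblup()] or [fit_wgblup()].
#' @param geno_new a complete [genotype_matrix()] of genotypes to predict.
#' @param trait trait label attached to the result.
#' @return A [bv_set()] over the genotypes of `geno_new`.
#' @export
predict_gebv <- function(model, geno_new, trait = "trait") {
  absent <- setdiff(model$marker_ids, marker_ids(geno_new))
  if (length(absent)) {
    stop("markers required by the model are absent: ",
         paste(utils::head(absent, 5), collapse = ", "),
         if (length(absent) > 5) sprintf(" (+%d more)", length(absent) - 5))
  }
  X <- geno_new$dosage[, model$marker_ids, drop = FALSE]
  if (anyNA(X)) stop("dosage matrix contains missing calls; impute first")
  W <- .center_dosage(X, model$freq)
  vals <- model$intercept + as.numeric(W %*% model$marker_effects)
  bv_set(stats::setNames(vals, genotype_ids(geno_new)), trait = trait)
}

#' Cross-validated predictive ability
#'
#' Repeated seeded k-fold cross-validation: per repeat, genotypes are
#' partitioned into k folds, the model is refitted excluding each held-out
#' fold, and the predictive ability is the Pearson correlation between the
#' pooled held-out predictions and the observed phenotypes.
#'
#' @param geno a complete [genotype_matrix()].
#' @param pheno named numeric phenotype vector.
#' @param k folds per repeat.
#' @param repeats number of repeated partitions.
#' @param seed integer seed controlling the fold assignments.
#' @param method `"rrblup"` (default) or `"wgblup"`.
#' @return A list of class `predictive_ability` with `r` (per-repeat Pearson
#'   correlations), `mean_r`, and `folds` (repeats x genotypes matrix of fold
#'   labels).
#' @export
cross_validate <- function(geno, pheno, k = 10L, repeats = 10L, seed = 1L,
                           method = c("rrblup", "wgblup")) {
  method <- match.arg(method)
  pheno <- .check_alignment(geno, pheno)
  n <- length(pheno)
  if (n < 2 * k) {
    stop(sprintf("n = %d is too small for %d-fold CV; reduce k", n, k))
  }
  sub <- geno[match(names(pheno), genotype_ids(geno)), ]
  fit_fun <- if (method == "rrblup") fit_rrblup else fit_wgblup
  .with_seed(seed, {
    folds <- matrix(0L, repeats, n, dimnames = list(NULL, names(pheno)))
    r <- numeric(repeats)
    for (rep_i in seq_len(repeats)) {
      fold <- sample(rep(seq_len(k), length.out = n))
      folds[rep_i, ] <- fold
      pred <- rep(NA_real_, n)
      for (f in seq_len(k)) {
        hold <- fold == f
        model <- fit_fun(sub[!hold, ], pheno[!hold])
        pred[hold] <- predict_gebv(model, sub[hold, ])$values
      }
      r[rep_i] <- stats::cor(pred, pheno)
    }
    structure(list(method = method, k = k, repeats = repeats, seed = seed,
                   r = r, mean_r = mean(r), folds = folds),
              class = "predictive_ability")
  })
}

#' @export
print.predictive_ability <- function(x, ...) {
  cat(sprintf("predictive ability (%s, %d-fold x %d): mean r = %.3f (range %.3f-%.3f)\n",
              x$method, x$k, x$repeats, x$mean_r, min(x$r), max(x$r)))
  invisible(x)
}

#' Phenology-adjusted yield
#'
#' Residuals of the ordinary least-squares regression of genotype yields on
#' onset of flowering: a phenology-independent yield measure that separates
#' drought resistance from drought escape by earliness. Residuals sum to
#' zero and are orthogonal to the flowering vector. When flowering has zero
#' variance the regression is undefined and centred yields are returned with
#' a warning.
#'
#' @param yield_values,flowering_values equal-length numeric vectors
#'   (names, if any, are preserved).
#' @return Numeric vector of adjusted yields, with attribute
#'   `zero_flowering_variance` set to `TRUE` in the degenerate case.
#' @export
adjusted_yield <- function(yield_values, flowering_values) {
  if (length(yield_values) != length(flowering_values)) {
    stop("yield and flowering vectors must have equal length")
  }
  if (length(yield_values) < 3) stop("at least 3 genotypes are required")
  if (stats::sd(flowering_values) == 0) {
    warning("flowering has zero variance; returning centred yields")
    out <- yield_values - mean(yield_values)
    attr(out, "zero_flowering_variance") <- TRUE
    return(out)
  }
  fit <- stats::lm(yield_values ~ flowering_values)
  out <- stats::setNames(as.numeric(stats::residuals(fit)),
                         names(yield_values))
  out
}
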