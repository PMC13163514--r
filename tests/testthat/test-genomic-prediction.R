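# rrBLUP / GBLUP / WGBLUP machinery, cross-validation, adjusted yield.

make_pop <- function(seed = 20, n_markers = 150, lines_per_cross = 10,
                     qtl_count = 40) {
  cfg <- simulation_config(seed = seed, n_markers = n_markers,
                           qtl_count = qtl_count)
  list(cfg = cfg,
       geno = simulate_factorial_cross_population(cfg, lines_per_cross = lines_per_cross),
       arch = simulate_trait_architecture(cfg, "grain_yield"))
}

test_that("rrBLUP matches the closed-form ridge solution at fixed lambda", {
  p <- make_pop()
  for (seed in 1:3) {
    withr::with_seed(seed, {
      idx <- sample(nrow(p$geno$dosage), 6)
      cols <- sample(ncol(p$geno$dosage), 4)
      sub <- p$geno[idx, cols]
      y <- setNames(rnorm(6), rownames(sub$dosage))
      lam <- runif(1, 0.5, 5)
      model <- fit_rrblup(sub, y, lambda = lam)
      # independent dense solve of the ridge normal equations
      W <- scale(sub$dosage, scale = FALSE)
      u_oracle <- solve(crossprod(W) + lam * diag(4), crossprod(W, y - mean(y)))
      expect_equal(unname(model$marker_effects), as.numeric(u_oracle),
                   tolerance = 1e-10)
      expect_equal(model$intercept, mean(y), tolerance = 1e-10)
    })
  }
})

test_that("rrBLUP degenerate and noise-free limits behave", {
  p <- make_pop()
  sub <- p$geno[1:20, ]
  y_const <- setNames(rep(4.2, 20), rownames(sub$dosage))
  m <- fit_rrblup(sub, y_const)
  expect_equal(unname(m$marker_effects), rep(0, ncol(sub$dosage)))
  expect_equal(m$intercept, 4.2)
  expect_equal(unname(predict_gebv(m, sub)$values), rep(4.2, 20))

  # noise-free additive trait is recovered essentially exactly in-sample
  # (training size large enough for REML to drive the residual to zero)
  sub <- p$geno[1:120, ]
  gv <- as.numeric(sub$dosage %*% p$arch$effects)
  y <- setNames(gv, rownames(sub$dosage))
  m2 <- fit_rrblup(sub, y)
  expect_gt(cor(m2$fitted, y), 0.999)
  # predicting the training set reproduces the fitted values
  expect_equal(predict_gebv(m2, sub)$values, m2$fitted, tolerance = 1e-9)

  expect_error(fit_rrblup(sub, setNames(rnorm(3), c("x", "y", "z"))), "absent")
  expect_error(fit_rrblup(p$geno[1:2, ], setNames(rnorm(2), rownames(p$geno$dosage)[1:2])),
               "at least 3")
})

test_that("a genotype at the training allele frequencies predicts the intercept", {
  # training set with column-mean dosage 1 at every marker
  m <- rbind(G1 = c(0, 0, 2), G2 = c(2, 2, 0), G3 = c(0, 2, 1),
             G4 = c(2, 0, 1))
  colnames(m) <- paste0("M", 1:3)
  g <- genotype_matrix(m)
  y <- setNames(c(1, 2, 3, 4), rownames(m))
  model <- fit_rrblup(g, y)
  new <- genotype_matrix(matrix(1, 1, 3, dimnames = list("NEW", colnames(m))))
  expect_equal(unname(predict_gebv(model, new)$values), model$intercept,
               tolerance = 1e-9)
  # marker mismatch is a named error
  expect_error(predict_gebv(model, g[, 1:2]), "M3")
})

test_that("GEBVs of unphenotyped genotypes track true genetic values", {
  p <- make_pop(seed = 21, n_markers = 300, lines_per_cross = 15)  # 240 lines
  gv <- as.numeric(p$geno$dosage %*% p$arch$effects)
  gv <- (gv - mean(gv)) / sd(gv)
  withr::with_seed(7, {
    y <- setNames(gv + rnorm(240, 0, sqrt(0.4 / 0.6)),  # h2 = 0.6
                  rownames(p$geno$dosage))
    train <- sort(sample(240, 150))
  })
  model <- fit_rrblup(p$geno[train, ], y[train])
  pred <- predict_gebv(model, p$geno[-train, ])
  expect_gt(cor(pred$values, gv[-train]), 0.5)
  # bv_set bookkeeping: stored m and s match the stored values
  expect_equal(pred$m, mean(pred$values))
  expect_equal(pred$s, sd(pred$values))
})

test_that("GRM matches a brute-force construction and its invariants", {
  p <- make_pop()
  sub <- p$geno[1:5, 1:8]
  G <- make_grm(sub)
  # brute-force double loop over genotype pairs
  X <- sub$dosage
  freq <- colMeans(X) / 2
  W <- sweep(X, 2, 2 * freq)
  denom <- 2 * sum(freq * (1 - freq))
  G_oracle <- matrix(0, 5, 5)
  for (i in 1:5) {
    for (j in 1:5) G_oracle[i, j] <- sum(W[i, ] * W[j, ]) / denom
  }
  expect_equal(unname(G), G_oracle, tolerance = 1e-12)
  expect_equal(G, t(G))
  # unit weights equal the unweighted construction
  expect_equal(make_grm(sub, weights = rep(1, 8)), G)
  # duplicated genotypes give identical rows/columns
  dup <- genotype_matrix(rbind(X, DUP = X[1, ]))
  G2 <- make_grm(dup)
  expect_equal(unname(G2["DUP", ]), unname(G2[1, ]))
  # all-monomorphic input has no defined GRM
  mono <- genotype_matrix(matrix(2, 4, 3, dimnames = list(paste0("G", 1:4),
                                                          paste0("M", 1:3))))
  expect_error(make_grm(mono), "monomorphic")
})

test_that("weighted GBLUP reduces to rrBLUP at unit weights", {
  for (seed in c(31, 32)) {
    p <- make_pop(seed = seed, n_markers = 120, lines_per_cross = 4)  # n < p
    gv <- as.numeric(p$geno$dosage %*% p$arch$effects)
    withr::with_seed(seed, {
      y <- setNames(scale(gv)[, 1] + rnorm(length(gv), 0, 0.8),
                    rownames(p$geno$dosage))
    })
    m_rr <- fit_rrblup(p$geno, y)
    m_gb <- fit_wgblup(p$geno, y, weights = rep(1, ncol(p$geno$dosage)))
    gebv_rr <- predict_gebv(m_rr, p$geno)$values
    gebv_gb <- predict_gebv(m_gb, p$geno)$values
    expect_lt(max(abs(gebv_rr - gebv_gb)), 1e-6 * sd(y))
  }
})

test_that("WGBLUP weights single out a planted major QTL", {
  cfg <- simulation_config(seed = 33, n_markers = 100, qtl_count = 0)
  pop <- simulate_factorial_cross_population(cfg, lines_per_cross = 8)
  # trait driven by one clearly segregating marker only
  mk <- unname(which(apply(pop$dosage, 2, sd) > 0.5)[1])
  y <- setNames(as.numeric(pop$dosage[, mk]) +
                  withr::with_seed(5, rnorm(nrow(pop$dosage), 0, 0.1)),
                rownames(pop$dosage))
  m <- fit_wgblup(pop, y)
  expect_equal(unname(which.max(m$marker_weights)), mk)
  expect_equal(mean(m$marker_weights), 1, tolerance = 1e-9)
  # constant phenotype: all GEBVs equal the intercept
  y0 <- setNames(rep(1.5, nrow(pop$dosage)), rownames(pop$dosage))
  m0 <- fit_wgblup(pop, y0)
  expect_equal(unname(predict_gebv(m0, pop)$values),
               rep(1.5, nrow(pop$dosage)))
})

test_that("shrinkage is monotone: huge lambda flattens effects to the mean", {
  p <- make_pop()
  sub <- p$geno[1:40, ]
  withr::with_seed(3, {
    y <- setNames(rnorm(40, 3, 1), rownames(sub$dosage))
  })
  m_inf <- fit_rrblup(sub, y, lambda = 1e10)
  expect_lt(max(abs(m_inf$marker_effects)), 1e-5)
  expect_equal(unname(predict_gebv(m_inf, sub)$values), rep(mean(y), 40),
               tolerance = 1e-4)
})

test_that("cross-validation is seeded, calibrated under the null, and powerful", {
  # null-simulation oracle: independent pure-noise datasets. Pooled-r CV
  # carries a small negative bias (held-out fold means anti-correlate with
  # the training mean); with 20 genotypes per fold it is well inside the
  # Monte-Carlo band around zero.
  r_bar <- vapply(1:10, function(s) {
    cfg <- simulation_config(seed = 500 + s, n_markers = 80)
    pop <- simulate_landrace_collection(cfg, n_accessions = 50,
                                        genotypes_per_accession = 4)
    y <- withr::with_seed(s, setNames(rnorm(200), rownames(pop$dosage)))
    cross_validate(pop, y, k = 10, repeats = 2, seed = s)$mean_r
  }, numeric(1))
  se <- sd(r_bar) / sqrt(length(r_bar))
  expect_lt(abs(mean(r_bar)), 3 * se)
  # noise-free additive signal with identifiable effects (p < n): mean r > 0.9
  p <- make_pop(seed = 22, n_markers = 60, lines_per_cross = 10,
                qtl_count = 20)  # 160 lines
  gv <- as.numeric(p$geno$dosage %*% p$arch$effects)
  y_sig <- setNames(gv, rownames(p$geno$dosage))
  cv_sig <- cross_validate(p$geno, y_sig, k = 5, repeats = 3, seed = 3)
  expect_gt(cv_sig$mean_r, 0.9)
  # determinism and fold bookkeeping
  cv_rep <- cross_validate(p$geno, y_sig, k = 5, repeats = 3, seed = 3)
  expect_identical(cv_sig$folds, cv_rep$folds)
  expect_identical(cv_sig$r, cv_rep$r)
  expect_true(all(apply(cv_sig$folds, 1, function(f) all(sort(unique(f)) == 1:5))))
  expect_error(cross_validate(p$geno, y_sig, k = 90), "reduce k")
})

test_that("predictive ability grows with training-set size", {
  margin <- matrix(NA_real_, 20, 2, dimnames = list(NULL, c("n50", "n150")))
  for (s in 1:20) {
    p <- make_pop(seed = 100 + s, n_markers = 120, lines_per_cross = 13) # 208
    gv <- as.numeric(p$geno$dosage %*% p$arch$effects)
    gv <- (gv - mean(gv)) / sd(gv)
    withr::with_seed(s, {
      y <- setNames(gv + rnorm(208, 0, sqrt(0.4 / 0.6)),
                    rownames(p$geno$dosage))
      test_idx <- sample(208, 50)
    })
    rest <- setdiff(seq_len(208), test_idx)
    for (jj in c(1, 2)) {
      n_tr <- c(50, 150)[jj]
      tr <- rest[seq_len(n_tr)]
      m <- fit_rrblup(p$geno[tr, ], y[tr])
      margin[s, jj] <- cor(predict_gebv(m, p$geno[test_idx, ])$values,
                           gv[test_idx])
    }
  }
  expect_gt(mean(margin[, "n150"]), mean(margin[, "n50"]))
})

test_that("adjusted yield is the least-squares residual of yield on flowering", {
  # zero-covariance construction: slope estimate is 0, residual = centred yield
  f <- c(1, 2, 3, 4)
  y <- c(1, 2, 2, 1)
  expect_equal(unname(adjusted_yield(y, f)), y - mean(y), tolerance = 1e-12)
  # perfectly collinear toy data: all residuals 0
  f2 <- c(10, 12, 15, 18, 20)
  expect_equal(unname(adjusted_yield(2 * f2 + 1, f2)), rep(0, 5),
               tolerance = 1e-12)
  # 5-point instance vs the normal-equation solve
  withr::with_seed(8, {
    f3 <- rnorm(5, 16, 2)
    y3 <- 0.3 * f3 + rnorm(5)
  })
  X <- cbind(1, f3)
  beta <- solve(crossprod(X), crossprod(X, y3))
  expect_equal(unname(adjusted_yield(y3, f3)),
               as.numeric(y3 - X %*% beta), tolerance = 1e-10)
  # residuals sum to zero and are orthogonal to flowering
  for (s in 1:5) {
    withr::with_seed(s, {
      ff <- rnorm(30, 16, 1.5)
      yy <- 3.5 + 0.2 * ff + rnorm(30, 0, 0.4)
    })
    r <- adjusted_yield(yy, ff)
    expect_lt(abs(sum(r)), 1e-8)
    expect_lt(abs(sum(r * ff)), 1e-8 * length(r) * sd(ff) * sd(yy))
  }
  # degenerate flowering: centred yields with a warning
  expect_warning(az <- adjusted_yield(c(1, 2, 3), c(5, 5, 5)), "zero variance")
  expect_equal(unname(az), c(-1, 0, 1), ignore_attr = TRUE)
  expect_true(attr(az, "zero_flowering_variance"))
  expect_error(adjusted_yield(1:4, 1:3), "equal length")
})
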