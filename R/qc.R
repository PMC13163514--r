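#' Per-marker and per-genotype quality statistics
#'
#' Computes, for each marker, the missing-call rate, the heterozygosity
#' (fraction of non-missing calls equal to dosage 1), the minor-allele
#' frequency among non-missing calls and a monomorphic flag (MAF = 0, which
#' includes all-missing markers); and, for each genotype, the missing-call
#' rate. These are the statistics behind the standard GBS filters
#' (marker missing rate < 0.3, genotype missing rate < 0.5,
#' heterozygosity < 0.3, no monomorphic markers).
#'
#' @param geno a [genotype_matrix()].
#' @return A list of class `marker_stats` with data frames `marker`
#'   (`marker_id`, `missing_rate`, `het`, `maf`, `monomorphic`) and
#'   `genotype` (`genotype_id`, `missing_rate`).
#' @export
compute_marker_stats <- function(geno) {
  X <- geno$dosage
  if (length(X) == 0L) stop("empty genotype matrix")
  miss <- is.na(X)
  n_obs <- colSums(!miss)
  het <- ifelse(n_obs > 0, colSums(X == 1, na.rm = TRUE) / n_obs, 0)
  freq <- ifelse(n_obs > 0, colMeans(X, na.rm = TRUE) / 2, NA_real_)
  maf <- ifelse(n_obs > 0, pmin(freq, 1 - freq), 0)
  maf[is.na(maf)] <- 0
  mono <- maf == 0
  structure(list(
    marker = data.frame(marker_id = marker_ids(geno),
                        missing_rate = colMeans(miss),
                        het = het, maf = maf, monomorphic = mono,
                        stringsAsFactors = FALSE),
    genotype = data.frame(genotype_id = genotype_ids(geno),
                          missing_rate = rowMeans(miss),
                          stringsAsFactors = FALSE)
  ), class = "marker_stats")
}

#' Filter a dosage matrix on missingness, heterozygosity and polymorphism
#'
#' Applies the marker-level filters first (drop monomorphic markers, then
#' markers with missing rate or heterozygosity at or above their thresholds),
#' then recomputes genotype missing rates on the retained markers and drops
#' genotypes at or above the genotype threshold. Threshold semantics are
#' strict `<` for retention, so an item exactly at a threshold is removed.
#' Each removed item is reported once with the highest-priority reason
#' (monomorphic > missing rate > heterozygosity).
#'
#' @param geno a [genotype_matrix()].
#' @param stats optional precomputed [compute_marker_stats()] for `geno`.
#' @param marker_miss_max,genotype_miss_max,het_max retention thresholds.
#' @param drop_monomorphic drop markers with zero minor-allele frequency.
#' @return A list with `geno` (the filtered [genotype_matrix()]) and
#'   `report` (data frame: `item`, `type`, `reason`, `value`).
#' @export
filter_genotype_matrix <- function(geno, stats = NULL,
                                   marker_miss_max = 0.3,
                                   genotype_miss_max = 0.5,
                                   het_max = 0.3,
                                   drop_monomorphic = TRUE) {
  for (th in c(marker_miss_max, genotype_miss_max, het_max)) {
    if (!is.numeric(th) || th < 0 || th > 1) {
      stop("thresholds must lie in [0, 1]")
    }
  }
  if (is.null(stats)) stats <- compute_marker_stats(geno)
  mk <- stats$marker
  reason <- rep(NA_character_, nrow(mk))
  value <- rep(NA_real_, nrow(mk))
  if (drop_monomorphic) {
    sel <- mk$monomorphic
    reason[sel] <- "monomorphic"
    value[sel] <- mk$maf[sel]
  }
  sel <- is.na(reason) & mk$missing_rate >= marker_miss_max
  reason[sel] <- "marker_missing_rate"
  value[sel] <- mk$missing_rate[sel]
  sel <- is.na(reason) & mk$het >= het_max
  reason[sel] <- "heterozygosity"
  value[sel] <- mk$het[sel]
  keep_mk <- is.na(reason)
  report <- data.frame(item = mk$marker_id[!keep_mk],
                       type = rep("marker", sum(!keep_mk)),
                       reason = reason[!keep_mk], value = value[!keep_mk],
                       stringsAsFactors = FALSE)
  kept <- geno[, keep_mk]
  # genotype filter uses missing rates on the retained marker set
  g_miss <- if (ncol(kept$dosage) > 0) rowMeans(is.na(kept$dosage)) else
    rep(0, nrow(kept$dosage))
  keep_gt <- g_miss < genotype_miss_max
  if (any(!keep_gt)) {
    report <- rbind(report, data.frame(
      item = genotype_ids(kept)[!keep_gt],
      type = rep("genotype", sum(!keep_gt)),
      reason = rep("genotype_missing_rate", sum(!keep_gt)),
      value = g_miss[!keep_gt],
      stringsAsFactors = FALSE))
  }
  list(geno = kept[keep_gt, ], report = report)
}

#' Deterministic k-nearest-genotype imputation of missing calls
#'
#' Replaces each missing call by the modal dosage of the `k_neighbors`
#' genotypes most similar to the target genotype that carry a non-missing
#' call at that marker; similarity is the fraction of identical calls among
#' mutually observed markers. Falls back to the marker's modal dosage when
#' no informative neighbour exists. Observed calls are never altered, ties
#' resolve towards the smaller dosage, and the procedure is fully
#' deterministic — unlike random-forest imputers it gives bit-identical
#' results on every run and platform.
#'
#' @param geno a [genotype_matrix()].
#' @param k_neighbors neighbourhood size.
#' @return A complete [genotype_matrix()] (no missing values).
#' @export
impute_missing <- function(geno, k_neighbors = 10L) {
  .assert_count(k_neighbors, "k_neighbors")
  X <- geno$dosage
  miss <- is.na(X)
  if (!any(miss)) return(geno)
  all_missing <- colSums(!miss) == 0L
  if (any(all_missing)) {
    stop("marker(s) with no observed calls cannot be imputed: ",
         paste(marker_ids(geno)[all_missing], collapse = ", "))
  }
  M <- !miss
  I0 <- M & X == 0; I0[is.na(I0)] <- FALSE
  I1 <- M & X == 1; I1[is.na(I1)] <- FALSE
  I2 <- M & X == 2; I2[is.na(I2)] <- FALSE
  storage.mode(I0) <- "double"; storage.mode(I1) <- "double"
  storage.mode(I2) <- "double"
  Mn <- M; storage.mode(Mn) <- "double"
  agree <- I0 %*% t(I0) + I1 %*% t(I1) + I2 %*% t(I2)
  comp <- Mn %*% t(Mn)
  sim <- agree / pmax(comp, 1)
  diag(sim) <- -Inf
  ord <- apply(sim, 2, order, decreasing = TRUE)  # ord[, i]: neighbours of i
  out <- X
  for (j in which(colSums(miss) > 0L)) {
    obs_mask <- M[, j]
    marker_mode <- .dosage_mode(X[obs_mask, j])
    for (i in which(miss[, j])) {
      nb <- ord[, i]
      nb <- nb[obs_mask[nb]]
      if (length(nb) == 0L) {
        out[i, j] <- marker_mode
      } else {
        nb <- nb[seq_len(min(k_neighbors, length(nb)))]
        out[i, j] <- .dosage_mode(X[nb, j])
      }
    }
  }
  genotype_matrix(out, chrom = geno$chrom, pos = geno$pos)
}

#' Write a QC removal report as CSV
#'
#' @param report removal report from [filter_genotype_matrix()].
#' @param path file path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
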