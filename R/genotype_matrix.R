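#' SNP dosage matrix container
#'
#' Wraps a genotypes x markers matrix of minor-allele dosages coded 0/1/2
#' (NA = missing call), with unique genotype and marker identifiers and
#' optional genomic coordinates. All QC, imputation and prediction functions
#' in the package operate on this container. Coordinates are metadata only;
#' no computation uses them.
#'
#' @param dosage numeric matrix, genotypes in rows, markers in columns;
#'   values must be 0, 1, 2 or NA.
#' @param genotype_ids character vector of unique row ids (defaults to
#'   rownames of `dosage`).
#' @param marker_ids character vector of unique column ids (defaults to
#'   colnames of `dosage`).
#' @param chrom,pos optional per-marker chromosome labels and positions.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, genotype_ids = rownames(dosage),
                            marker_ids = colnames(dosage),
                            chrom = NULL, pos = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(genotype_ids)) {
    genotype_ids <- paste0("G", seq_len(nrow(dosage)), recycle0 = TRUE)
  }
  if (is.null(marker_ids)) {
    marker_ids <- paste0("M", seq_len(ncol(dosage)), recycle0 = TRUE)
  }
  genotype_ids <- as.character(genotype_ids)
  marker_ids <- as.character(marker_ids)
  if (length(genotype_ids) != nrow(dosage)) {
    stop("length(genotype_ids) must equal nrow(dosage)")
  }
  if (length(marker_ids) != ncol(dosage)) {
    stop("length(marker_ids) must equal ncol(dosage)")
  }
  if (anyDuplicated(genotype_ids)) stop("genotype ids must be unique")
  if (anyDuplicated(marker_ids)) stop("marker ids must be unique")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) {
    stop(sprintf("dosage values must be 0, 1, 2 or NA (%d offending entries)",
                 sum(bad)))
  }
  if (!is.null(chrom) && length(chrom) != length(marker_ids)) {
    stop("chrom must have one entry per marker")
  }
  if (!is.null(pos) && length(pos) != length(marker_ids)) {
    stop("pos must have one entry per marker")
  }
  dimnames(dosage) <- list(genotype_ids, marker_ids)
  structure(list(dosage = dosage, chrom = chrom, pos = pos),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' @export
as.matrix.genotype_matrix <- function(x, ...) x$dosage

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- dim(x$dosage)
  miss <- mean(is.na(x$dosage))
  cat(sprintf("genotype_matrix: %d genotypes x %d markers (%.1f%% missing)\n",
              d[1], d[2], 100 * miss))
  invisible(x)
}

genotype_ids <- function(x) rownames(x$dosage)
marker_ids <- function(x) colnames(x$dosage)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i,j genotype (row) and marker (column) indices, ids or masks.
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  jn <- if (is.character(j)) match(j, colnames(x$dosage)) else seq_len(ncol(x$dosage))[j]
  genotype_matrix(x$dosage[i, j, drop = FALSE],
                  chrom = x$chrom[jn], pos = x$pos[jn])
}

#' Write/read a dosage matrix as tab-delimited text
#'
#' Plain genotypes x markers layout with a leading `genotype_id` column;
#' missing calls written as `NA`.
#'
#' @param geno a [genotype_matrix()].
#' @param path file path.
#' @return `write_genotype_matrix` returns `path` invisibly;
#'   `read_genotype_matrix` returns a [genotype_matrix()].
#' @export
write_genotype_matrix <- function(geno, path) {
  df <- data.frame(genotype_id = genotype_ids(geno), geno$dosage,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop(sprintf("'%s' contains no genotype records", path))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  genotype_matrix(m)
}

#' Write a minimal VCF (GT field only) from a dosage matrix
#'
#' Dosages are emitted as unphased diploid genotypes (0 -> 0/0, 1 -> 0/1,
#' 2 -> 1/1, NA -> ./.) with placeholder REF/ALT alleles when no coordinate
#' metadata is available. Suitable for interchange with standard VCF tools.
#'
#' @param geno a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(geno, path) {
  n_mark <- ncol(geno$dosage)
  chrom <- if (is.null(geno$chrom)) rep("1", n_mark) else as.character(geno$chrom)
  pos <- if (is.null(geno$pos)) seq_len(n_mark) else as.integer(geno$pos)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotype_ids(geno)), collapse = "\t")
  )
  body <- vapply(seq_len(n_mark), function(k) {
    calls <- geno$dosage[, k]
    gt <- ifelse(is.na(calls), "./.", gt_code[as.character(calls)])
    paste(c(chrom[k], pos[k], marker_ids(geno)[k], "A", "G", ".", ".", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}
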