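#' Genotype matrix container
#'
#' The central object of the pipeline: a samples x variants matrix of diploid
#' allele dosages (0 = homozygous reference, 1 = heterozygous, 2 = homozygous
#' alternate, `NA` = missing) together with per-variant coordinates and site
#' metadata, and a sample table carrying population labels.
#'
#' @param geno integer matrix, samples in rows, variants in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param variants data frame with one row per variant column and at least
#'   the columns `contig`, `pos` (1-based), `ref`, `alt`; optional site
#'   metadata columns `dp` (total read depth), `mq` (root-mean-square mapping
#'   quality) and `bq` (mean base quality of the alternate allele).
#' @param samples data frame with columns `sample` and `population`, one row
#'   per genotype-matrix row, in row order.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, variants, samples) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(variants) != ncol(geno))
    stop("variants table has ", nrow(variants), " rows but genotype matrix has ",
         ncol(geno), " columns")
  if (nrow(samples) != nrow(geno))
    stop("sample table has ", nrow(samples), " rows but genotype matrix has ",
         nrow(geno), " rows")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype dosages must be 0, 1, 2 or NA")
  req <- c("contig", "pos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variants table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(variants$pos < 1L)) stop("variant positions must be >= 1")
  dimnames(geno) <- list(samples$sample, NULL)
  structure(
    list(geno = geno,
         variants = as.data.frame(variants, stringsAsFactors = FALSE),
         samples = as.data.frame(samples, stringsAsFactors = FALSE)),
    class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix: ", nrow(x$geno), " samples x ", ncol(x$geno),
      " variants\n", sep = "")
  cat("contigs:", paste(unique(x$variants$contig), collapse = ", "), "\n")
  tab <- table(x$samples$population)
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by variant index
#'
#' @param gm a [geno_matrix()].
#' @param j integer or logical index over variant columns.
#' @return A `geno_matrix` restricted to the selected variants.
#' @export
subset_variants <- function(gm, j) {
  geno_matrix(gm$geno[, j, drop = FALSE],
              gm$variants[j, , drop = FALSE],
              gm$samples)
}

#' Row indices of the samples belonging to a population
#' @param gm a [geno_matrix()].
#' @param population population label as used in the sample table.
#' @return Integer vector of row indices.
#' @export
pop_rows <- function(gm, population) {
  idx <- which(gm$samples$population == population)
  if (!length(idx)) stop("no samples belong to population '", population, "'")
  idx
}

#' Per-site alternate-allele counts and called-allele totals
#'
#' @param gm a [geno_matrix()].
#' @param rows optional integer vector restricting to a subset of samples
#'   (default all).
#' @return A list with integer vectors `alt` (alternate allele count) and
#'   `n` (number of called alleles, i.e. twice the called genotypes) per
#'   variant.
#' @export
allele_counts <- function(gm, rows = seq_len(nrow(gm$geno))) {
  g <- gm$geno[rows, , drop = FALSE]
  called <- !is.na(g)
  alt <- colSums(g, na.rm = TRUE)
  n <- 2L * colSums(called)
  list(alt = as.integer(alt), n = as.integer(n))
}

#' Minor allele frequency per site
#'
#' Computed from called alleles only: sites where all genotypes are missing
#' return `NA`.
#'
#' @inheritParams allele_counts
#' @return Numeric vector of per-site minor allele frequencies.
#' @export
site_maf <- function(gm, rows = seq_len(nrow(gm$geno))) {
  ac <- allele_counts(gm, rows)
  p <- ifelse(ac$n > 0L, ac$alt / ac$n, NA_real_)
  pmin(p, 1 - p)
}
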