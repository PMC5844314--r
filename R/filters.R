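#' SNP filter criteria
#'
#' Thresholds of the high-quality SNP retention step.  Defaults: total
#' coverage depth >= 3 and <= 31,000 (the upper cap guards against collapsed
#' repeats), root-mean-square mapping quality >= 20, mean base quality of the
#' alternate allele >= 20, per-site genotype missingness <= 0.2, minor allele
#' frequency >= 0.05, and biallelic single-nucleotide records only.  All
#' boundaries are inclusive.
#'
#' @param min_depth minimum total site depth.
#' @param max_total_depth maximum total site depth.
#' @param min_rms_mq minimum RMS mapping quality.
#' @param min_base_quality minimum mean base quality of the variant allele.
#' @param max_missing_frac maximum fraction of missing genotypes at a site.
#' @param min_maf minimum minor allele frequency (computed from called
#'   alleles only).
#' @param biallelic_snps_only drop records whose REF/ALT are not single
#'   bases or that carry more than one alternate allele.
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_depth = 3,
                            max_total_depth = 31000,
                            min_rms_mq = 20,
                            min_base_quality = 20,
                            max_missing_frac = 0.2,
                            min_maf = 0.05,
                            biallelic_snps_only = TRUE) {
  if (any(c(min_depth, max_total_depth, min_rms_mq, min_base_quality) < 0))
    stop("thresholds must be non-negative")
  if (max_missing_frac < 0 || max_missing_frac > 1)
    stop("max_missing_frac must lie in [0,1]")
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must lie in [0, 0.5]")
  structure(list(min_depth = min_depth,
                 max_total_depth = max_total_depth,
                 min_rms_mq = min_rms_mq,
                 min_base_quality = min_base_quality,
                 max_missing_frac = max_missing_frac,
                 min_maf = min_maf,
                 biallelic_snps_only = biallelic_snps_only),
            class = "filter_criteria")
}

#' Apply SNP filters to a genotype matrix
#'
#' Records are tested against the criteria in a fixed order (biallelic SNP,
#' minimum depth, depth cap, mapping quality, base quality, missingness,
#' MAF); the report attributes each removal to the first criterion it fails,
#' so attribution depends on that order while the surviving set does not.
#' Sites with a missing metadata value pass the corresponding threshold
#' (treated as unannotated, not as failing).
#'
#' @param gm a [geno_matrix()].
#' @param criteria a [filter_criteria()].
#' @return A list with `matrix` (the filtered [geno_matrix()]) and `report`
#'   (data frame of per-criterion removal counts, plus the input/output
#'   totals as attributes).
#' @export
apply_filters <- function(gm, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  if (ncol(gm$geno) == 0) stop("empty genotype matrix")
  v <- gm$variants
  n <- nrow(v)
  pass_na <- function(x, test) is.na(x) | test

  is_snp <- nchar(v$ref) == 1L & nchar(v$alt) == 1L &
    !grepl(",", v$alt, fixed = TRUE) &
    v$ref %in% c("A", "C", "G", "T") & v$alt %in% c("A", "C", "G", "T")
  if (!criteria$biallelic_snps_only) is_snp <- rep(TRUE, n)

  dp <- if ("dp" %in% names(v)) v$dp else rep(NA_real_, n)
  mq <- if ("mq" %in% names(v)) v$mq else rep(NA_real_, n)
  bq <- if ("bq" %in% names(v)) v$bq else rep(NA_real_, n)
  miss_frac <- colMeans(is.na(gm$geno))
  maf <- site_maf(gm)

  checks <- list(
    biallelic_snp = is_snp,
    min_depth = pass_na(dp, dp >= criteria$min_depth),
    max_total_depth = pass_na(dp, dp <= criteria$max_total_depth),
    min_rms_mq = pass_na(mq, mq >= criteria$min_rms_mq),
    min_base_quality = pass_na(bq, bq >= criteria$min_base_quality),
    max_missing_frac = miss_frac <= criteria$max_missing_frac,
    min_maf = pass_na(maf, maf >= criteria$min_maf))

  keep <- rep(TRUE, n)
  removed <- integer(length(checks))
  names(removed) <- names(checks)
  for (i in seq_along(checks)) {
    fail_here <- keep & !checks[[i]]
    removed[i] <- sum(fail_here)
    keep <- keep & checks[[i]]
  }
  report <- data.frame(criterion = names(removed),
                       removed = as.integer(removed),
                       stringsAsFactors = FALSE)
  attr(report, "n_input") <- n
  attr(report, "n_retained") <- sum(keep)
  list(matrix = subset_variants(gm, keep), report = report)
}

#' Write a filter report as TSV
#' @param report the report component of [apply_filters()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  df <- rbind(report,
              data.frame(criterion = c("total_input", "total_retained"),
                         removed = c(attr(report, "n_input"),
                                     attr(report, "n_retained"))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
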