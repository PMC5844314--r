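#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses diploid GT fields into allele dosages (0/1/2, `NA` for missing) and
#' carries the per-site `DP`, `MQ` and `BQ` INFO annotations used by the
#' filter stage.
#'
#' @param path VCF file (v4.x, plain text or bgzipped).
#' @param population_map data frame with columns `sample` and `population`,
#'   or the path of a two-column tab-separated file (no header required if
#'   the columns are named `sample`/`population`; otherwise first column =
#'   sample, second = population).  Every VCF sample must appear in the map.
#' @return A [geno_matrix()] with samples in VCF order.
#' @export
read_vcf <- function(path, population_map) {
  if (is.character(population_map))
    population_map <- read_population_map(population_map)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = 1,
                                     dimnames = list(names(gt), NULL))
  vcf_samples <- colnames(vcf@gt)[-1]
  missing_samples <- setdiff(vcf_samples, population_map$sample)
  if (length(missing_samples))
    stop("sample(s) absent from population map: ",
         paste(missing_samples, collapse = ", "))

  dosage <- dosage_from_gt(gt)           # variants x samples
  info <- parse_info(fix$INFO)
  variants <- data.frame(
    contig = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    dp = info$DP, mq = info$MQ, bq = info$BQ,
    stringsAsFactors = FALSE)
  samples <- population_map[match(vcf_samples, population_map$sample), ]
  rownames(samples) <- NULL
  geno_matrix(t(dosage), variants, samples)
}

dosage_from_gt <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  d[clean %in% c("0/0")] <- 0L
  d[clean %in% c("0/1", "1/0")] <- 1L
  d[clean %in% c("1/1")] <- 2L
  d
}

parse_info <- function(info) {
  get_num <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    out <- rep(NA_real_, length(info))
    hit <- grepl(paste0("(^|;)", key, "="), info)
    out[hit] <- as.numeric(sub(paste0(".*", key, "="), "",
                               regmatches(info, regexpr(
                                 paste0("(^|;)", key, "=[^;]+"), info))))
    out
  }
  list(DP = get_num("DP"), MQ = get_num("MQ"), BQ = get_num("BQ"))
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits diploid unphased GT fields and per-site `DP`, `MQ` and `BQ` INFO
#' annotations.  Output is plain text and byte-stable for a given input.
#'
#' @param gm a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    sprintf("##contig=<ID=%s>", unique(v$contig)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Mean base quality of alternate allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(gm$geno), ncol(gm$geno))
  ok <- !is.na(gm$geno)
  gt[ok] <- gt_code[gm$geno[ok] + 1L]
  info <- sprintf("DP=%d;MQ=%s;BQ=%s",
                  as.integer(round(ifelse(is.na(v$dp), 0, v$dp))),
                  format(v$mq, trim = TRUE), format(v$bq, trim = TRUE))
  body <- paste(v$contig, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a sample-to-population map
#'
#' Two tab-separated columns: sample id and population label.
#'
#' @param path file path.
#' @return A data frame with columns `sample` and `population`.
#' @export
read_population_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (identical(tolower(unlist(df[1, ])), c("sample", "population")))
    df <- df[-1, , drop = FALSE]
  names(df)[1:2] <- c("sample", "population")
  rownames(df) <- NULL
  df[, 1:2]
}

#' @rdname read_population_map
#' @param map data frame with columns `sample` and `population`.
#' @export
write_population_map <- function(map, path) {
  utils::write.table(map[, c("sample", "population")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write and read simulation ground truth
#'
#' A single tab-separated file: `##sweep` header lines carry the planted
#' sweep intervals, followed by a per-variant table of coordinates, alleles'
#' transition status, ancestral frequency and per-population frequencies.
#' `read_truth(write_truth(x, p))` reproduces `x` up to numeric formatting
#' (frequencies are written with 10 significant digits).
#'
#' @param truth a `sim_truth` object from [simulate_dataset()].
#' @param path output path.
#' @return `path` invisibly (`write_truth`); a `sim_truth` (`read_truth`).
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sw <- truth$sweep_intervals
  if (!is.null(sw) && nrow(sw)) {
    for (i in seq_len(nrow(sw)))
      writeLines(sprintf("##sweep\t%s\t%d\t%d\t%d\t%.10g\t%.10g",
                         sw$contig[i], as.integer(sw$start[i]),
                         as.integer(sw$end[i]), as.integer(sw$target_pop[i]),
                         sw$F_sweep[i], sw$diversity_scale[i]), con)
  }
  df <- data.frame(contig = truth$contig, pos = truth$pos,
                   is_transition = as.integer(truth$is_transition),
                   p_anc = signif(truth$ancestral_freqs, 10),
                   signif(truth$pop_freqs, 10),
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  sw_lines <- grep("^##sweep\t", lines, value = TRUE)
  sweep_intervals <- NULL
  if (length(sw_lines)) {
    parts <- do.call(rbind, strsplit(sw_lines, "\t"))
    sweep_intervals <- data.frame(
      contig = parts[, 2], start = as.numeric(parts[, 3]),
      end = as.numeric(parts[, 4]), target_pop = as.integer(parts[, 5]),
      F_sweep = as.numeric(parts[, 6]),
      diversity_scale = as.numeric(parts[, 7]),
      stringsAsFactors = FALSE)
  }
  body <- lines[!grepl("^##", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  pop_cols <- setdiff(names(df), c("contig", "pos", "is_transition", "p_anc"))
  structure(
    list(ancestral_freqs = df$p_anc,
         pop_freqs = as.matrix(df[, pop_cols, drop = FALSE]),
         is_transition = df$is_transition == 1L,
         sweep_intervals = sweep_intervals,
         contig = df$contig, pos = df$pos),
    class = "sim_truth")
}
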