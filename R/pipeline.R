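#' Pipeline configuration
#'
#' Collects the inputs and stage parameters of an end-to-end run: filter the
#' VCF, annotate against the gene models, scan target vs reference windows
#' for sweeps, build the NJ tree and PCA over all samples, compute per-
#' population LD decay, and (when a term map is given) test the sweep genes
#' for enrichment.
#'
#' @param vcf path to the multi-sample VCF.
#' @param gff3 path to the GFF3 gene models (optional; skips annotation and
#'   gene assignment when `NULL`).
#' @param population_map path to the sample-to-population TSV, or a data
#'   frame.
#' @param reference_fasta optional path to a reference FASTA for codon-level
#'   annotation (required when `gff3` is given).
#' @param term_map_path optional gene-to-term TSV for enrichment.
#' @param pop_target,pop_reference populations contrasted by the sweep scan;
#'   `pop_outgroup` is carried for the tree/PCA only.
#' @param criteria a [filter_criteria()].
#' @param window_size,window_step sweep-scan window geometry in bp.
#' @param top_frac joint upper-tail fraction for outlier calling.
#' @param ld_max_distance,ld_bin_width LD-decay settings in bp.
#' @param bootstrap_replicates NJ bootstrap replicates.
#' @param seed root seed; per-stage seeds are derived from it and recorded
#'   in the run manifest.
#' @param out_dir output directory (created if absent).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, population_map, out_dir,
                            gff3 = NULL, reference_fasta = NULL,
                            term_map_path = NULL,
                            pop_target, pop_reference, pop_outgroup = NULL,
                            criteria = filter_criteria(),
                            window_size = 40000, window_step = 20000,
                            top_frac = 0.05,
                            ld_max_distance = 500000, ld_bin_width = 10000,
                            bootstrap_replicates = 100,
                            seed = 1L) {
  map <- if (is.character(population_map)) read_population_map(population_map)
         else population_map
  pops <- unique(map$population)
  for (p in c(pop_target, pop_reference, pop_outgroup))
    if (!p %in% pops)
      stop("population '", p, "' not present in the population map")
  if (!is.null(gff3) && is.null(reference_fasta))
    stop("codon-level annotation needs reference_fasta alongside gff3")
  structure(list(vcf = vcf, gff3 = gff3, population_map = map,
                 reference_fasta = reference_fasta,
                 term_map_path = term_map_path,
                 pop_target = pop_target, pop_reference = pop_reference,
                 pop_outgroup = pop_outgroup,
                 criteria = criteria,
                 window_size = window_size, window_step = window_step,
                 top_frac = top_frac,
                 ld_max_distance = ld_max_distance,
                 ld_bin_width = ld_bin_width,
                 bootstrap_replicates = bootstrap_replicates,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes filter -> annotate -> scan -> tree -> PCA -> LD -> enrichment
#' and writes all outputs plus a JSON run manifest into `config$out_dir`.
#' Identical config and inputs give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return The output directory, invisibly; per-stage objects are attached
#'   as the attribute `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stage_seed <- derive_seeds(config$seed)
  counts <- list()

  gm <- read_vcf(config$vcf, config$population_map)
  counts$n_input_snps <- ncol(gm$geno)

  flt <- apply_filters(gm, config$criteria)
  gm_f <- flt$matrix
  counts$n_filtered_snps <- ncol(gm_f$geno)
  if (counts$n_filtered_snps == 0) stop("stage filter: no SNPs survive")
  write_vcf(gm_f, out("filtered.vcf"))
  write_filter_report(flt$report, out("filter_report.tsv"))

  tstv <- ts_tv_counts(gm_f)
  counts$tstv_ratio <- tstv$ratio

  models <- NULL
  if (!is.null(config$gff3)) {
    models <- read_gff3(config$gff3)
    ref <- Biostrings::readDNAStringSet(config$reference_fasta)
    names(ref) <- sub("\\s.*", "", names(ref))
    ann <- classify_variants(gm_f, models, ref)
    write_annotation(ann, out("annotation.tsv"))
    counts$annotation <- as.list(table(ann$category))
  }

  contig_lengths <- contig_lengths_from(gm_f)
  windows <- make_windows(contig_lengths, config$window_size,
                          config$window_step)
  if (!nrow(windows)) stop("stage scan: no full window fits any contig")
  stats <- window_stats(gm_f, config$pop_target, config$pop_reference,
                        windows)
  called <- call_sweep_regions(stats, top_frac = config$top_frac)
  regions <- called$regions
  if (!is.null(models)) regions <- assign_genes(regions, models)
  write_window_stats(called$stats, out("window_stats.tsv"))
  write_sweep_bed(regions, out("sweep_regions.bed"))
  counts$n_windows <- nrow(stats)
  counts$n_outlier_windows <- sum(called$stats$is_outlier)
  counts$n_sweep_regions <- nrow(regions)
  sweep_genes <- attr(regions, "unique_genes")
  if (!is.null(models)) {
    counts$n_sweep_genes <- length(sweep_genes)
    writeLines(sweep_genes, out("sweep_genes.txt"))
  }

  tree <- bootstrap_supports(gm_f, config$bootstrap_replicates,
                             seed = stage_seed["tree"])
  to_newick(tree, out("tree.nwk"))
  write_phylip(suppressMessages(p_distance(gm_f)), out("distances.phylip"))

  pc <- pca(gm_f, n_components = 3)
  write_pca(pc, gm_f, out("pca.tsv"))
  counts$pc_var_explained <- as.list(signif(pc$var_explained, 6))

  ld <- list()
  for (p in unique(gm_f$samples$population)) {
    curve <- decay_curve(gm_f, p, max_distance = config$ld_max_distance,
                         bin_width = config$ld_bin_width,
                         seed = stage_seed["ld"])
    write_decay_curve(curve, out(sprintf("ld_decay_%s.tsv", p)))
    ld[[p]] <- curve
  }

  enr <- NULL
  if (!is.null(config$term_map_path) && !is.null(models) &&
      length(sweep_genes)) {
    tm <- read_term_map(config$term_map_path)
    enr <- binomial_enrichment(sweep_genes, tm)
    write_enrichment(enr, out("enrichment.tsv"))
    counts$n_terms_fdr05 <- sum(enr$fdr_adjusted_p < 0.05)
  }

  manifest <- list(
    package = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    seed = config$seed,
    stage_seeds = as.list(stage_seed),
    parameters = list(
      pop_target = config$pop_target, pop_reference = config$pop_reference,
      window_size = config$window_size, window_step = config$window_step,
      top_frac = config$top_frac,
      ld_max_distance = config$ld_max_distance,
      ld_bin_width = config$ld_bin_width,
      bootstrap_replicates = config$bootstrap_replicates,
      filter = unclass(config$criteria)),
    counts = counts)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  res <- list(matrix = gm_f, filter_report = flt$report, tstv = tstv,
              window_stats = called$stats, regions = regions,
              sweep_genes = sweep_genes, tree = tree, pca = pc, ld = ld,
              enrichment = enr)
  invisible(structure(config$out_dir, results = res))
}

# per-stage seeds derived from the root seed (kept below 2^31)
derive_seeds <- function(seed) {
  c(tree = (seed * 1000003L + 11L) %% .Machine$integer.max,
    ld = (seed * 1000003L + 23L) %% .Machine$integer.max)
}

contig_lengths_from <- function(gm) {
  tapply(gm$variants$pos, gm$variants$contig, max)
}

#' Score recovery of simulation ground truth
#'
#' Compares pipeline outputs against the planted truth of a simulated
#' dataset: bp-level Jaccard overlap of called sweep regions with the
#' planted intervals, bias of the mean window FST against a stated expected
#' value, Ts/Tv recovery error, and the mean silhouette width of the target
#' population on PC1 (1 = perfectly separated, <= 0 = mixed).
#'
#' @param results the `results` attribute of a [run_pipeline()] return, or
#'   an equivalent list with `window_stats`, `regions`, `tstv`, `pca` and
#'   `matrix`.
#' @param truth a `sim_truth` (for the planted sweep intervals).
#' @param expected_fst expected genome-wide FST (the shared Balding-Nichols
#'   F of target and reference); `NA` skips the bias field.
#' @param expected_tstv expected transition/transversion ratio.
#' @param pop_target target population label.
#' @return A list: `sweep_jaccard` (`NA` when the truth has no sweeps),
#'   `fst_bias`, `tstv_error`, `pc1_silhouette`.
#' @export
score_recovery <- function(results, truth, expected_fst = NA,
                           expected_tstv = NA, pop_target) {
  sw <- truth$sweep_intervals
  jac <- if (is.null(sw) || !nrow(sw)) NA_real_
  else region_jaccard(results$regions, sw)

  mean_fst <- mean(results$window_stats$fst, na.rm = TRUE)
  fst_bias <- if (is.na(expected_fst)) NA_real_ else mean_fst - expected_fst
  tstv_err <- if (is.na(expected_tstv)) NA_real_
  else results$tstv$ratio - expected_tstv

  pc1 <- results$pca$coords[, 1]
  labels <- results$matrix$samples$population == pop_target
  list(sweep_jaccard = jac,
       mean_window_fst = mean_fst,
       fst_bias = fst_bias,
       tstv_ratio = results$tstv$ratio,
       tstv_error = tstv_err,
       pc1_silhouette = silhouette_1d(pc1, labels))
}

# bp Jaccard between called regions (0-based half-open) and planted
# intervals (1-based inclusive)
region_jaccard <- function(regions, sweeps) {
  per_contig <- function(cname) {
    r <- regions[regions$contig == cname, , drop = FALSE]
    s <- sweeps[sweeps$contig == cname, , drop = FALSE]
    called <- interval_union(r$start, r$end)
    planted <- interval_union(s$start - 1, s$end)
    list(inter = interval_intersect_len(called, planted),
         union = interval_len(called) + interval_len(planted) -
           interval_intersect_len(called, planted))
  }
  contigs <- union(regions$contig, sweeps$contig)
  parts <- lapply(contigs, per_contig)
  inter <- sum(vapply(parts, `[[`, numeric(1), "inter"))
  uni <- sum(vapply(parts, `[[`, numeric(1), "union"))
  if (uni == 0) return(NA_real_)
  inter / uni
}

interval_union <- function(start, end) {
  if (!length(start)) return(cbind(start = numeric(0), end = numeric(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ks <- ke <- numeric(0)
  cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ce) ce <- max(ce, end[i])
    else { ks <- c(ks, cs); ke <- c(ke, ce); cs <- start[i]; ce <- end[i] }
  }
  cbind(start = c(ks, cs), end = c(ke, ce))
}

interval_len <- function(iv) sum(iv[, "end"] - iv[, "start"])

interval_intersect_len <- function(a, b) {
  total <- 0
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      total <- total + max(0, min(a[i, "end"], b[j, "end"]) -
                             max(a[i, "start"], b[j, "start"]))
  total
}

# mean silhouette width of the TRUE class along one coordinate
silhouette_1d <- function(x, is_target) {
  if (!any(is_target) || all(is_target)) return(NA_real_)
  s <- vapply(which(is_target), function(i) {
    a <- mean(abs(x[i] - x[is_target][-match(i, which(is_target))]))
    if (is.nan(a)) a <- 0
    b <- mean(abs(x[i] - x[!is_target]))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
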