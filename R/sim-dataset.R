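#' Simulate a multi-population genotype dataset
#'
#' Draws variant positions at the configured density, ancestral allele
#' frequencies Uniform(floor, 1 - floor), Balding-Nichols population
#' frequencies Beta(p(1-F)/F, (1-p)(1-F)/F), and diploid genotypes as the sum
#' of two haplotypes.  Inside a planted sweep interval the target population's
#' ancestral draw is rescaled toward fixation (p' = 1 - diversity_scale *
#' (1 - p)) and its drift coefficient replaced by `F_sweep`, producing the
#' classic sweep signature of elevated differentiation and depressed
#' diversity.  Linkage disequilibrium is induced by first-order copying of
#' the latent uniform that thresholds each haplotype allele: with probability
#' exp(-d / ld_block_scale) a site reuses its left neighbour's uniform, which
#' leaves the per-site allele frequency exactly Bernoulli(pop frequency)
#' while correlating nearby sites.
#'
#' @param config a [sim_config()].
#' @return A list with elements `matrix` (a [geno_matrix()]) and `truth`
#'   (class `sim_truth`: per-variant ancestral frequencies, per-population
#'   frequency matrix, transition flags, and the configured sweep intervals).
#' @examples
#' cfg <- sim_config(n_pops = 2, samples_per_pop = c(10, 10),
#'                   contigs = c(chr1 = 2e5), F_per_pop = c(0.1, 0.1),
#'                   seed = 7)
#' sim <- simulate_dataset(cfg)
#' sim$matrix
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  n_pops <- config$n_pops
  n_per <- config$samples_per_pop
  n_samples <- sum(n_per)
  pop_of_sample <- rep(seq_len(n_pops), n_per)
  sample_ids <- unlist(lapply(seq_len(n_pops), function(k)
    sprintf("%s_s%02d", config$pop_labels[k], seq_len(n_per[k]))))

  var_list <- list()
  geno_list <- list()
  freq_list <- list()
  anc_list <- list()
  ts_list <- list()

  for (ci in seq_along(config$contigs)) {
    cname <- names(config$contigs)[ci]
    clen <- config$contigs[[ci]]
    n_var <- stats::rpois(1, clen * config$snp_density)
    if (n_var < 1) next
    n_var <- min(n_var, clen)
    pos <- sort(sample.int(clen, n_var))

    p_anc <- stats::runif(n_var, config$maf_floor_ancestral,
                          1 - config$maf_floor_ancestral)
    is_ts <- stats::runif(n_var) < config$tstv_ratio / (1 + config$tstv_ratio)
    alleles <- draw_alleles(n_var, is_ts)

    # per-population frequencies: Balding-Nichols around the ancestral draw
    f_eff <- matrix(rep(config$F_per_pop, each = n_var), n_var, n_pops)
    p_eff <- matrix(rep(p_anc, n_pops), n_var, n_pops)
    sw <- config$sweep_intervals
    if (!is.null(sw)) {
      for (i in seq_len(nrow(sw))) {
        if (sw$contig[i] != cname) next
        hit <- pos >= sw$start[i] & pos <= sw$end[i]
        k <- sw$target_pop[i]
        f_eff[hit, k] <- sw$F_sweep[i]
        p_eff[hit, k] <- 1 - sw$diversity_scale[i] * (1 - p_anc[hit])
      }
    }
    pop_freq <- matrix(0, n_var, n_pops)
    for (k in seq_len(n_pops)) {
      a <- p_eff[, k] * (1 - f_eff[, k]) / f_eff[, k]
      b <- (1 - p_eff[, k]) * (1 - f_eff[, k]) / f_eff[, k]
      pop_freq[, k] <- stats::rbeta(n_var, a, b)
    }

    # haplotype copying: probability of reusing the previous latent uniform
    copy_p <- c(0, exp(-diff(pos) / config$ld_block_scale))
    geno <- matrix(0L, n_samples, n_var)
    for (s in seq_len(n_samples)) {
      fq <- pop_freq[, pop_of_sample[s]]
      hap <- integer(n_var)
      for (h in 1:2) {
        fresh <- stats::runif(n_var) >= copy_p
        fresh[1] <- TRUE
        draws <- stats::runif(n_var)
        src <- cummax(seq_len(n_var) * fresh)
        hap <- hap + as.integer(draws[src] < fq)
      }
      geno[s, ] <- hap
    }
    if (config$missing_rate > 0) {
      drop <- matrix(stats::runif(length(geno)) < config$missing_rate,
                     n_samples, n_var)
      geno[drop] <- NA_integer_
    }

    dp <- stats::rpois(n_var, config$depth_mean * n_samples)
    mq <- round(stats::rnorm(n_var, config$mq_mean, 2), 2)
    bq <- round(stats::rnorm(n_var, config$bq_mean, 1.5), 2)

    var_list[[cname]] <- data.frame(
      contig = cname, pos = pos, ref = alleles$ref, alt = alleles$alt,
      dp = dp, mq = mq, bq = bq, stringsAsFactors = FALSE)
    geno_list[[cname]] <- geno
    freq_list[[cname]] <- pop_freq
    anc_list[[cname]] <- p_anc
    ts_list[[cname]] <- is_ts
  }
  if (!length(var_list)) stop("no variants simulated; increase snp_density")

  variants <- do.call(rbind, var_list)
  rownames(variants) <- NULL
  gm <- geno_matrix(do.call(cbind, geno_list), variants,
                    data.frame(sample = sample_ids,
                               population = config$pop_labels[pop_of_sample],
                               stringsAsFactors = FALSE))
  pf <- do.call(rbind, freq_list)
  colnames(pf) <- config$pop_labels
  truth <- structure(
    list(ancestral_freqs = unlist(anc_list, use.names = FALSE),
         pop_freqs = pf,
         is_transition = unlist(ts_list, use.names = FALSE),
         sweep_intervals = config$sweep_intervals,
         contig = variants$contig, pos = variants$pos),
    class = "sim_truth")
  list(matrix = gm, truth = truth)
}

# REF/ALT pairs consistent with the transition flag.  Transitions are the
# purine<->purine and pyrimidine<->pyrimidine changes A<->G and C<->T.
draw_alleles <- function(n, is_ts) {
  bases <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_partners <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))
  ref <- bases[sample.int(4, n, replace = TRUE)]
  alt <- character(n)
  alt[is_ts] <- ts_partner[ref[is_ts]]
  n_tv <- sum(!is_ts)
  if (n_tv) {
    pick <- sample.int(2, n_tv, replace = TRUE)
    alt[!is_ts] <- mapply(function(r, k) tv_partners[[r]][k],
                          ref[!is_ts], pick, USE.NAMES = FALSE)
  }
  list(ref = ref, alt = alt)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", length(x$ancestral_freqs), "variants,",
      ncol(x$pop_freqs), "populations,",
      if (is.null(x$sweep_intervals)) 0 else nrow(x$sweep_intervals),
      "sweep intervals\n")
  invisible(x)
}
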