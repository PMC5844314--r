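#' Simulation configuration
#'
#' Parameters of the Balding-Nichols genotype simulator.  Population allele
#' frequencies are drawn around an ancestral frequency p from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), so the expected Hudson FST between two
#' populations sharing a drift coefficient F is approximately F — an analytic
#' calibration target for the downstream scan.  Planted sweep intervals push
#' the target population toward fixation (elevated differentiation, reduced
#' diversity); first-order haplotype copying induces linkage disequilibrium
#' that decays with physical distance.
#'
#' @param n_pops number of populations.
#' @param samples_per_pop integer vector of length `n_pops`: diploid sample
#'   counts per population.
#' @param contigs named numeric vector of contig lengths in bp.
#' @param snp_density expected SNPs per bp (default 1/300, about one variant
#'   every few hundred bp as seen in deep mammalian resequencing).
#' @param F_per_pop drift coefficient per population, each in (0, 1).
#' @param sweep_intervals data frame with columns `contig`, `start`, `end`
#'   (1-based inclusive bp), `target_pop` (population index), `F_sweep`
#'   (drift inside the sweep, must exceed the target population's background
#'   F) and `diversity_scale` in (0, 1] (how strongly the ancestral
#'   frequency is pulled toward fixation; smaller = stronger sweep).
#'   May be `NULL` for no sweeps.
#' @param tstv_ratio expected transition/transversion ratio of simulated
#'   mutations (default 2.57, typical of filtered mammalian SNP sets).
#' @param maf_floor_ancestral ancestral frequencies are drawn
#'   Uniform(`maf_floor_ancestral`, 1 - `maf_floor_ancestral`); the default
#'   0.05 means most sites survive a MAF >= 0.05 filter by design.
#' @param missing_rate per-genotype missingness probability in [0, 1).
#' @param ld_block_scale bp scale of the haplotype-copying correlation: a
#'   haplotype reuses its previous site's latent uniform with probability
#'   exp(-d / ld_block_scale) for inter-site distance d.
#' @param depth_mean expected per-sample read depth used to simulate the
#'   per-site total-depth (`DP`) annotation.
#' @param mq_mean,bq_mean means of the simulated root-mean-square mapping
#'   quality and base quality site annotations; defaults pass the default
#'   filter thresholds.
#' @param pop_labels character labels per population (default "pop1", ...).
#' @param seed integer random seed.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_dataset()]
#' @export
sim_config <- function(n_pops = 3,
                       samples_per_pop = c(6, 20, 4),
                       contigs = c(contig1 = 1e6),
                       snp_density = 1 / 300,
                       F_per_pop = c(0.12, 0.10, 0.18),
                       sweep_intervals = NULL,
                       tstv_ratio = 2.57,
                       maf_floor_ancestral = 0.05,
                       missing_rate = 0.02,
                       ld_block_scale = 5000,
                       depth_mean = 7,
                       mq_mean = 50,
                       bq_mean = 32,
                       pop_labels = paste0("pop", seq_len(n_pops)),
                       seed = 1L) {
  if (n_pops < 1) stop("need at least one population")
  if (length(samples_per_pop) != n_pops)
    stop("samples_per_pop must have length n_pops")
  if (any(samples_per_pop < 1)) stop("all sample counts must be positive")
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("contigs must be a named vector of lengths")
  if (any(contigs < 1)) stop("zero-length contig")
  if (length(F_per_pop) != n_pops) stop("F_per_pop must have length n_pops")
  if (any(F_per_pop <= 0 | F_per_pop >= 1)) stop("F values must lie in (0,1)")
  if (tstv_ratio <= 0) stop("tstv_ratio must be positive")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0,1)")
  if (maf_floor_ancestral < 0 || maf_floor_ancestral >= 0.5)
    stop("maf_floor_ancestral must lie in [0, 0.5)")
  if (length(pop_labels) != n_pops) stop("pop_labels must have length n_pops")
  if (!is.null(sweep_intervals)) {
    sweep_intervals <- as.data.frame(sweep_intervals)
    req <- c("contig", "start", "end", "target_pop", "F_sweep",
             "diversity_scale")
    if (!all(req %in% names(sweep_intervals)))
      stop("sweep_intervals needs columns: ", paste(req, collapse = ", "))
    for (i in seq_len(nrow(sweep_intervals))) {
      sw <- sweep_intervals[i, ]
      if (!sw$contig %in% names(contigs))
        stop("sweep interval on unknown contig '", sw$contig, "'")
      if (sw$start < 1 || sw$end > contigs[[sw$contig]] || sw$start > sw$end)
        stop("sweep interval outside its contig")
      if (sw$target_pop < 1 || sw$target_pop > n_pops)
        stop("sweep target_pop out of range")
      if (sw$F_sweep <= F_per_pop[sw$target_pop])
        stop("F_sweep must exceed the target population's background F")
      if (sw$diversity_scale <= 0 || sw$diversity_scale > 1)
        stop("diversity_scale must lie in (0, 1]")
    }
  }
  structure(
    list(n_pops = as.integer(n_pops),
         samples_per_pop = as.integer(samples_per_pop),
         contigs = contigs,
         snp_density = snp_density,
         F_per_pop = F_per_pop,
         sweep_intervals = sweep_intervals,
         tstv_ratio = tstv_ratio,
         maf_floor_ancestral = maf_floor_ancestral,
         missing_rate = missing_rate,
         ld_block_scale = ld_block_scale,
         depth_mean = depth_mean,
         mq_mean = mq_mean,
         bq_mean = bq_mean,
         pop_labels = pop_labels,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_pops, "populations (",
      paste(sprintf("%s: n=%d, F=%.3g", x$pop_labels, x$samples_per_pop,
                    x$F_per_pop), collapse = "; "), ")\n")
  cat("contigs:", paste(sprintf("%s (%g bp)", names(x$contigs), x$contigs),
                        collapse = ", "), "\n")
  cat(sprintf("snp_density=%.4g/bp  tstv=%.3g  missing=%.3g  ld_scale=%g bp  seed=%d\n",
              x$snp_density, x$tstv_ratio, x$missing_rate, x$ld_block_scale,
              x$seed))
  n_sw <- if (is.null(x$sweep_intervals)) 0L else nrow(x$sweep_intervals)
  cat("planted sweeps:", n_sw, "\n")
  invisible(x)
}
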