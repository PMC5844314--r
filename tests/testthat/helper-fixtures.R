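# Small in-code fixtures shared across tests.

# a geno_matrix from a bare dosage matrix (one contig, evenly spaced sites)
toy_gm <- function(geno, populations = rep("popA", nrow(geno)),
                   pos = seq_len(ncol(geno)) * 100L,
                   contig = "chr1",
                   ref = rep("A", ncol(geno)), alt = rep("G", ncol(geno)),
                   dp = rep(100, ncol(geno)), mq = rep(60, ncol(geno)),
                   bq = rep(35, ncol(geno))) {
  geno_matrix(
    geno,
    data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
               dp = dp, mq = mq, bq = bq, stringsAsFactors = FALSE),
    data.frame(sample = sprintf("s%02d", seq_len(nrow(geno))),
               population = populations, stringsAsFactors = FALSE))
}

# exhaustive average-pairwise-difference diversity for one window,
# counting differing allele pairs site by site (independent of site_pi)
brute_window_pi <- function(gm, population, window) {
  rows <- which(gm$samples$population == population)
  idx <- which(gm$variants$contig == window$contig &
                 gm$variants$pos > window$start &
                 gm$variants$pos <= window$end)
  total <- 0
  any_ok <- FALSE
  for (s in idx) {
    g <- gm$geno[rows, s]
    g <- g[!is.na(g)]
    alleles <- unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
    n <- length(alleles)
    if (n < 2) next
    any_ok <- TRUE
    diffs <- 0
    for (i in seq_len(n - 1))
      for (j in (i + 1):n)
        diffs <- diffs + (alleles[i] != alleles[j])
    total <- total + diffs / choose(n, 2)
  }
  if (length(idx) == 0) return(0)
  if (!any_ok) return(NA_real_)
  unname(total / (window$end - window$start))
}

# per-site Hudson components summed over a window, written independently
brute_window_fst <- function(gm, pop1, pop2, window) {
  r1 <- which(gm$samples$population == pop1)
  r2 <- which(gm$samples$population == pop2)
  idx <- which(gm$variants$contig == window$contig &
                 gm$variants$pos > window$start &
                 gm$variants$pos <= window$end)
  num <- den <- 0
  for (s in idx) {
    g1 <- gm$geno[r1, s]; g1 <- g1[!is.na(g1)]
    g2 <- gm$geno[r2, s]; g2 <- g2[!is.na(g2)]
    n1 <- 2 * length(g1); n2 <- 2 * length(g2)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(g1) / n1; p2 <- sum(g2) / n2
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  if (den == 0) return(NA_real_)
  unname(num / den)
}

# random unrooted additive tree and its path-length matrix (ape oracle)
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 2)
  list(tree = tr, dist = ape::cophenetic.phylo(tr))
}

# the 10-record filter fixture: 4 clean records plus exactly one violation
# of each of the six criteria (depth floor, depth cap, mapping quality,
# base quality, missingness, MAF)
filter_fixture <- function() {
  n_samples <- 10
  geno <- matrix(rep(c(0L, 1L, 1L, 2L, 0L), 2), n_samples, 10)
  geno[, 7] <- c(rep(NA_integer_, 3), rep(1L, 7))     # 30% missing > 0.2
  geno[, 8] <- rep(0L, 10)                            # MAF 0 < 0.05
  dp <- rep(100, 10); mq <- rep(60, 10); bq <- rep(35, 10)
  dp[5] <- 2          # below depth floor 3
  dp[6] <- 40000      # above cap 31000
  mq[9] <- 10         # below RMS MQ 20
  bq[10] <- 15        # below base quality 20
  toy_gm(geno, populations = rep("popA", n_samples),
         dp = dp, mq = mq, bq = bq)
}

# tiny simulated dataset used by several tests
small_sim <- function(seed = 1, n1 = 10, n2 = 10, len = 2e5, F = 0.1,
                      density = 1 / 300, ...) {
  cfg <- sim_config(n_pops = 2, samples_per_pop = c(n1, n2),
                    contigs = c(chr1 = len), F_per_pop = c(F, F),
                    snp_density = density, seed = seed, ...)
  simulate_dataset(cfg)
}
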