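#' Pairwise r-squared between two sites from unphased genotypes
#'
#' Default is the composite (Rogers-Huff) measure: the squared Pearson
#' correlation of the dosage vectors over pairwise-complete samples, which
#' needs no phase information.  `method = "em"` instead estimates the four
#' two-locus haplotype frequencies by expectation-maximisation from the
#' 3 x 3 genotype counts and returns D^2 / (pA qA pB qB); on genotypes
#' collapsed from phased haplotypes this matches the phased r^2.
#'
#' @param a,b dosage vectors (0/1/2, `NA` missing) of the two sites.
#' @param method `"composite"` (default) or `"em"`.
#' @param max_iter,tol EM iteration controls.
#' @return r-squared in [0, 1]; `NA` when either site is monomorphic among
#'   the complete pairs.
#' @export
pair_r2 <- function(a, b, method = c("composite", "em"),
                    max_iter = 100, tol = 1e-10) {
  method <- match.arg(method)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) stop("need >= 2 samples called at both sites")
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  if (method == "composite") {
    return(stats::cor(a, b)^2)
  }
  em_haplotype_r2(a, b, max_iter, tol)
}

# EM for two-locus haplotype frequency pAB from unphased genotype counts.
# Only the double heterozygote is phase-ambiguous.
em_haplotype_r2 <- function(a, b, max_iter = 100, tol = 1e-10) {
  n <- length(a)
  pA <- mean(a) / 2
  pB <- mean(b) / 2
  # known haplotype contributions: each individual contributes 2 haplotypes;
  # for all genotype combinations except 1/1 the AB haplotype count is fixed
  n11 <- sum(a == 1 & b == 1)
  # AB haplotypes certain: min(a,b) per individual works for unambiguous cells
  fixed_ab <- sum(pmin(a, b)[!(a == 1 & b == 1)])
  pAB <- pA * pB
  for (it in seq_len(max_iter)) {
    D <- pAB - pA * pB
    p_cis <- pAB * (1 - pA - pB + pAB)            # AB/ab phase
    p_trans <- (pA - pAB) * (pB - pAB)            # Ab/aB phase
    frac <- if (p_cis + p_trans > 0) p_cis / (p_cis + p_trans) else 0.5
    new_pAB <- (fixed_ab + n11 * frac) / (2 * n)
    if (abs(new_pAB - pAB) < tol) { pAB <- new_pAB; break }
    pAB <- new_pAB
  }
  D <- pAB - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (denom == 0) return(NA_real_)
  min(1, D^2 / denom)
}

#' Distance-binned LD decay curve
#'
#' For one population, computes r-squared for intra-contig SNP pairs closer
#' than `max_distance`, after restricting to sites with minor allele
#' frequency above `min_maf` within that population, and averages within
#' contiguous distance bins.  Dense datasets can be subsampled to at most
#' `max_pairs_per_bin` pairs per bin (reproducibly via `seed`); set it to
#' `Inf` for full enumeration.
#'
#' @param gm a [geno_matrix()].
#' @param population population label.
#' @param max_distance maximum pair separation in bp (default 500 kb, the
#'   genome-averaging window).
#' @param bin_width bin width in bp (default 10 kb).
#' @param min_maf per-population MAF threshold for eligible sites.
#' @param method r-squared flavour, see [pair_r2()].
#' @param max_pairs_per_bin subsampling cap per bin (default 2000).
#' @param seed integer seed for the subsampling.
#' @return Data frame with `bin_start`, `bin_end` (half-open bp), `mean_r2`,
#'   `n_pairs`; empty (with a warning) when no pair is eligible.
#' @export
decay_curve <- function(gm, population, max_distance = 500000,
                        bin_width = 10000, min_maf = 0.05,
                        method = "composite",
                        max_pairs_per_bin = 2000, seed = 1L) {
  rows <- pop_rows(gm, population)
  maf <- site_maf(gm, rows)
  keep <- !is.na(maf) & maf > min_maf
  sub <- subset_variants(gm, keep)
  g <- sub$geno[rows, , drop = FALSE]
  v <- sub$variants

  pairs_i <- integer(0); pairs_j <- integer(0)
  for (cname in unique(v$contig)) {
    idx <- which(v$contig == cname)
    if (length(idx) < 2) next
    pos <- v$pos[idx]
    # for each left site, right partners within max_distance
    hi <- findInterval(pos + max_distance - 1e-9, pos)
    counts <- pmax(hi - seq_along(pos), 0L)
    i_rep <- rep(seq_along(pos), counts)
    j_rep <- unlist(lapply(seq_along(pos), function(k)
      if (counts[k] > 0) (k + 1):hi[k] else integer(0)))
    pairs_i <- c(pairs_i, idx[i_rep])
    pairs_j <- c(pairs_j, idx[j_rep])
  }
  bins <- data.frame(bin_start = seq(0, max_distance - bin_width,
                                     by = bin_width))
  bins$bin_end <- bins$bin_start + bin_width
  bins$mean_r2 <- NA_real_
  bins$n_pairs <- 0L
  if (!length(pairs_i)) {
    warning("no eligible SNP pairs within max_distance")
    return(bins)
  }
  dist <- v$pos[pairs_j] - v$pos[pairs_i]
  bin_of <- pmin(dist %/% bin_width + 1L, nrow(bins))
  set.seed(seed)
  for (b in seq_len(nrow(bins))) {
    sel <- which(bin_of == b)
    if (!length(sel)) next
    if (is.finite(max_pairs_per_bin) && length(sel) > max_pairs_per_bin)
      sel <- sample(sel, max_pairs_per_bin)
    r2 <- if (method == "composite")
      composite_r2_pairs(g, pairs_i[sel], pairs_j[sel])
    else vapply(sel, function(k)
      pair_r2(g[, pairs_i[k]], g[, pairs_j[k]], method = method),
      numeric(1))
    r2 <- r2[!is.na(r2)]
    bins$n_pairs[b] <- length(r2)
    if (length(r2)) bins$mean_r2[b] <- mean(r2)
  }
  bins
}

# vectorized squared Pearson correlation over many site pairs with
# pairwise-complete handling; NA for monomorphic pairs
composite_r2_pairs <- function(g, i_idx, j_idx) {
  a <- g[, i_idx, drop = FALSE]
  b <- g[, j_idx, drop = FALSE]
  m <- !is.na(a) & !is.na(b)
  a[!m] <- 0L
  b[!m] <- 0L
  n <- colSums(m)
  sa <- colSums(a); sb <- colSums(b)
  saa <- colSums(a * a); sbb <- colSums(b * b); sab <- colSums(a * b)
  va <- n * saa - sa^2
  vb <- n * sbb - sb^2
  cov <- n * sab - sa * sb
  out <- rep(NA_real_, length(i_idx))
  ok <- n >= 2 & va > 0 & vb > 0
  out[ok] <- (cov[ok]^2) / (va[ok] * vb[ok])
  out
}

#' Half-decay distance of an LD curve
#'
#' The midpoint of the first bin whose mean r-squared falls to half of the
#' first (shortest-distance) bin's mean, or `NA` when the curve never
#' reaches that level.
#'
#' @param curve a decay curve from [decay_curve()].
#' @return Distance in bp, or `NA`.
#' @export
half_decay_distance <- function(curve) {
  def <- which(!is.na(curve$mean_r2))
  if (!length(def)) stop("curve has no defined bins")
  r0 <- curve$mean_r2[def[1]]
  hit <- def[curve$mean_r2[def] <= r0 / 2]
  if (!length(hit)) return(NA_real_)
  (curve$bin_start[hit[1]] + curve$bin_end[hit[1]]) / 2
}

#' Write an LD decay curve as TSV
#' @param curve a decay curve from [decay_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decay_curve <- function(curve, path) {
  df <- curve
  df$mean_r2 <- signif(df$mean_r2, 8)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
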