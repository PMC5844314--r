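#' Per-site nucleotide diversity
#'
#' Unbiased mean pairwise difference at one site:
#' 2 p (1-p) n / (n-1) for alternate-allele frequency p among n called
#' alleles.  Equals the fraction of differing pairs among all C(n,2) allele
#' pairs.
#'
#' @param alt_count alternate allele count at the site.
#' @param n_alleles number of called alleles (>= 2).
#' @return Per-site diversity in [0, 1].
#' @export
site_pi <- function(alt_count, n_alleles) {
  if (any(n_alleles < 2)) stop("site_pi requires at least 2 called alleles")
  if (any(alt_count < 0 | alt_count > n_alleles))
    stop("alt_count must lie in [0, n_alleles]")
  p <- alt_count / n_alleles
  2 * p * (1 - p) * n_alleles / (n_alleles - 1)
}

#' Hudson's per-site FST components
#'
#' Returns the numerator and denominator of Hudson's estimator for one site:
#' numerator (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1), denominator
#' p1(1-p2) + p2(1-p1).  Window-level FST combines sites as a ratio of sums
#' ("ratio of averages"), which is robust to low-information sites.
#'
#' @param p1,p2 alternate-allele frequencies in the two populations.
#' @param n1,n2 called allele counts (>= 2 each).
#' @return A list with `numerator` and `denominator` (vectors).
#' @export
hudson_fst_site <- function(p1, n1, p2, n2) {
  if (any(n1 < 2 | n2 < 2)) stop("hudson_fst_site requires n >= 2 alleles")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(numerator = num, denominator = den)
}

#' Sliding windows over contigs
#'
#' Half-open windows `[start, start + size)` placed at `0, step, 2*step, ...`;
#' only windows fully inside the contig are emitted (truncated terminal
#' windows are dropped so the per-bp normalisation stays comparable).
#'
#' @param contig_lengths named numeric vector of contig lengths in bp.
#' @param size window size in bp (default 40 kb).
#' @param step window step in bp (default 20 kb, i.e. 50% overlap).
#' @return Data frame with `contig`, `start`, `end` (0-based half-open).
#' @export
make_windows <- function(contig_lengths, size = 40000, step = 20000) {
  if (size <= 0 || step <= 0 || step > size)
    stop("need size > 0 and 0 < step <= size")
  out <- lapply(names(contig_lengths), function(cname) {
    len <- contig_lengths[[cname]]
    if (len < size) return(NULL)
    starts <- seq(0, len - size, by = step)
    data.frame(contig = cname, start = starts, end = starts + size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(contig = character(), start = numeric(),
                                      end = numeric())
  rownames(out) <- NULL
  out
}

# indices of variants inside a half-open window (1-based positions)
window_sites <- function(gm, window) {
  which(gm$variants$contig == window$contig &
          gm$variants$pos > window$start &
          gm$variants$pos <= window$end)
}

#' Windowed nucleotide diversity
#'
#' Sum of per-site diversity over the SNPs in the window divided by the
#' window length in bp (invariant sites contribute zero), giving per-site
#' units.  Sites with fewer than 2 called alleles in the population are
#' skipped; a window where every site is uncallable returns `NA`.
#'
#' @param gm a [geno_matrix()].
#' @param population population label.
#' @param window one-row data frame / list with `contig`, `start`, `end`
#'   (0-based half-open).
#' @return Per-site diversity (>= 0), or `NA`.
#' @export
window_pi <- function(gm, population, window) {
  rows <- pop_rows(gm, population)
  idx <- window_sites(gm, window)
  if (!length(idx)) return(0)
  ac <- allele_counts(subset_variants(gm, idx), rows)
  ok <- ac$n >= 2
  if (!any(ok)) return(NA_real_)
  sum(site_pi(ac$alt[ok], ac$n[ok])) / (window$end - window$start)
}

#' Windowed Hudson FST
#'
#' Ratio of summed per-site numerators to summed denominators over the SNPs
#' in the window.  Windows with zero total denominator (no informative
#' sites) return `NA`.
#'
#' @inheritParams window_pi
#' @param pop_target,pop_reference the two population labels.
#' @return Window FST (<= 1, may be slightly negative by sampling noise),
#'   or `NA`.
#' @export
window_fst <- function(gm, pop_target, pop_reference, window) {
  idx <- window_sites(gm, window)
  if (!length(idx)) return(NA_real_)
  sub <- subset_variants(gm, idx)
  ac1 <- allele_counts(sub, pop_rows(gm, pop_target))
  ac2 <- allele_counts(sub, pop_rows(gm, pop_reference))
  ok <- ac1$n >= 2 & ac2$n >= 2
  if (!any(ok)) return(NA_real_)
  h <- hudson_fst_site(ac1$alt[ok] / ac1$n[ok], ac1$n[ok],
                       ac2$alt[ok] / ac2$n[ok], ac2$n[ok])
  den <- sum(h$denominator)
  if (den == 0) return(NA_real_)
  sum(h$numerator) / den
}

#' Window statistics for the sweep scan
#'
#' Computes, for every window, the SNP count, Hudson FST between target and
#' reference populations, per-site diversity in each, and the diversity
#' ratio reference/target (elevated values flag diversity loss in the
#' target, the sweep signature).
#'
#' @param gm a [geno_matrix()] (already filtered).
#' @param pop_target,pop_reference population labels; the scan contrasts the
#'   target (candidate selected) population against the reference panel.
#' @param windows window table from [make_windows()].
#' @return Data frame with one row per window: `contig`, `start`, `end`,
#'   `n_snps`, `fst`, `pi_target`, `pi_reference`, `pi_ratio`, `log2_ratio`.
#' @export
window_stats <- function(gm, pop_target, pop_reference, windows) {
  rows_t <- pop_rows(gm, pop_target)
  rows_r <- pop_rows(gm, pop_reference)
  n_win <- nrow(windows)
  res <- windows
  res$n_snps <- integer(n_win)
  res$fst <- res$pi_target <- res$pi_reference <- rep(NA_real_, n_win)

  # vectorized per-site quantities, then per-window aggregation
  ac_t <- allele_counts(gm, rows_t)
  ac_r <- allele_counts(gm, rows_r)
  ok_t <- ac_t$n >= 2
  ok_r <- ac_r$n >= 2
  pi_t <- ifelse(ok_t, site_pi(pmax(ac_t$alt, 0), pmax(ac_t$n, 2)), 0)
  pi_r <- ifelse(ok_r, site_pi(pmax(ac_r$alt, 0), pmax(ac_r$n, 2)), 0)
  both <- ok_t & ok_r
  num <- den <- numeric(ncol(gm$geno))
  if (any(both)) {
    h <- hudson_fst_site(ac_t$alt[both] / ac_t$n[both], ac_t$n[both],
                         ac_r$alt[both] / ac_r$n[both], ac_r$n[both])
    num[both] <- h$numerator
    den[both] <- h$denominator
  }
  contig <- gm$variants$contig
  pos <- gm$variants$pos
  for (w in seq_len(n_win)) {
    idx <- which(contig == res$contig[w] &
                   pos > res$start[w] & pos <= res$end[w])
    res$n_snps[w] <- length(idx)
    if (!length(idx)) {
      res$pi_target[w] <- res$pi_reference[w] <- 0
      next
    }
    L <- res$end[w] - res$start[w]
    res$pi_target[w] <- if (any(ok_t[idx])) sum(pi_t[idx]) / L else NA_real_
    res$pi_reference[w] <- if (any(ok_r[idx])) sum(pi_r[idx]) / L else NA_real_
    d <- sum(den[idx])
    res$fst[w] <- if (d > 0) sum(num[idx]) / d else NA_real_
  }
  res$pi_ratio <- ifelse(!is.na(res$pi_target) & res$pi_target > 0,
                         res$pi_reference / res$pi_target, NA_real_)
  res$log2_ratio <- ifelse(!is.na(res$pi_ratio) & res$pi_ratio > 0,
                           log2(res$pi_ratio), NA_real_)
  res
}

#' Call putative selective-sweep regions
#'
#' Z-standardises the log2 diversity ratio and a log-transformed,
#' positively shifted FST (shift = 1 - min(fst), so the smallest value maps
#' to log(1) = 0; set `log_transform_fst = FALSE` to Z-standardise raw FST
#' instead).  A window is an outlier when BOTH Z-scores lie at or above
#' their empirical (1 - `top_frac`) quantile (`joint = "intersection"`), or
#' when either does (`"union"`); overlapping or book-ended outlier windows
#' are merged into regions.
#'
#' @param stats window table from [window_stats()].
#' @param top_frac upper tail fraction (default 0.05).
#' @param joint `"intersection"` (default), `"union"`, `"fst"` or
#'   `"pi_ratio"` for single-statistic calling.
#' @param log_transform_fst log-transform the shifted FST before
#'   Z-standardising (default `TRUE`).
#' @return A list with `stats` (input plus `z_fst`, `z_log_ratio`,
#'   `is_outlier`) and `regions` (data frame `contig`, `start`, `end`,
#'   `n_windows`, `peak_z_fst`, `peak_z_log_ratio`).
#' @export
call_sweep_regions <- function(stats, top_frac = 0.05,
                               joint = c("intersection", "union", "fst",
                                         "pi_ratio"),
                               log_transform_fst = TRUE) {
  joint <- match.arg(joint)
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must lie in (0, 1]")
  ok <- !is.na(stats$fst) & !is.na(stats$log2_ratio)
  if (!any(ok)) stop("all window statistics are missing")
  if (sum(ok) < 20)
    warning("fewer than 20 windows with defined statistics; ",
            "empirical quantiles will be unstable")

  zscore <- function(x) (x - mean(x)) / stats::sd(x)
  fst_t <- if (log_transform_fst)
    log(stats$fst[ok] + (1 - min(stats$fst[ok]))) else stats$fst[ok]
  z_fst <- zscore(fst_t)
  z_lr <- zscore(stats$log2_ratio[ok])

  thr_fst <- stats::quantile(z_fst, 1 - top_frac, names = FALSE)
  thr_lr <- stats::quantile(z_lr, 1 - top_frac, names = FALSE)
  out_ok <- switch(joint,
    intersection = z_fst >= thr_fst & z_lr >= thr_lr,
    union = z_fst >= thr_fst | z_lr >= thr_lr,
    fst = z_fst >= thr_fst,
    pi_ratio = z_lr >= thr_lr)

  stats$z_fst <- stats$z_log_ratio <- rep(NA_real_, nrow(stats))
  stats$z_fst[ok] <- z_fst
  stats$z_log_ratio[ok] <- z_lr
  stats$is_outlier <- rep(FALSE, nrow(stats))
  stats$is_outlier[ok] <- out_ok

  list(stats = stats, regions = merge_outlier_windows(stats))
}

merge_outlier_windows <- function(stats) {
  out <- stats[stats$is_outlier, , drop = FALSE]
  if (!nrow(out))
    return(data.frame(contig = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      peak_z_fst = numeric(), peak_z_log_ratio = numeric()))
  out <- out[order(out$contig, out$start), ]
  regions <- list()
  cur <- out[1, ]
  cur_n <- 1L
  flush <- function(cur, cur_n) data.frame(
    contig = cur$contig, start = cur$start, end = cur$end,
    n_windows = cur_n, peak_z_fst = cur$z_fst,
    peak_z_log_ratio = cur$z_log_ratio, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))[-1]) {
    w <- out[i, ]
    if (w$contig == cur$contig && w$start <= cur$end) {
      cur$end <- max(cur$end, w$end)
      cur$z_fst <- max(cur$z_fst, w$z_fst)
      cur$z_log_ratio <- max(cur$z_log_ratio, w$z_log_ratio)
      cur_n <- cur_n + 1L
    } else {
      regions[[length(regions) + 1L]] <- flush(cur, cur_n)
      cur <- w
      cur_n <- 1L
    }
  }
  regions[[length(regions) + 1L]] <- flush(cur, cur_n)
  res <- do.call(rbind, regions)
  rownames(res) <- NULL
  res
}

#' Assign genes to sweep regions
#'
#' A gene is listed for a region when its transcript span intersects the
#' half-open region interval; `unique_genes` deduplicates across regions
#' for the global selected-gene count.
#'
#' @param regions region table from [call_sweep_regions()].
#' @param models a `gene_models` list.
#' @return `regions` with a `genes` list-column and an attribute
#'   `unique_genes` (character vector of distinct gene ids).
#' @export
assign_genes <- function(regions, models) {
  spans <- do.call(rbind, lapply(models, function(m) {
    rng <- range(c(m$exons[, 1], m$exons[, 2]))
    data.frame(gene_id = m$gene_id, contig = m$contig,
               start = rng[1], end = rng[2], stringsAsFactors = FALSE)
  }))
  genes <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    if (is.null(spans)) { genes[[i]] <- character(); next }
    hit <- spans$contig == regions$contig[i] &
      spans$start <= regions$end[i] &        # 1-based gene vs 0-based region
      spans$end > regions$start[i]
    genes[[i]] <- spans$gene_id[hit]
  }
  regions$genes <- genes
  attr(regions, "unique_genes") <- unique(unlist(genes))
  regions
}

#' Write window statistics and sweep regions
#'
#' @param stats annotated window table (from [call_sweep_regions()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_stats <- function(stats, path) {
  df <- stats
  num_cols <- vapply(df, is.numeric, logical(1))
  df[num_cols] <- lapply(df[num_cols], function(x) signif(x, 8))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_stats
#' @param regions region table, optionally with genes assigned.
#' @export
write_sweep_bed <- function(regions, path) {
  if (!nrow(regions)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  name <- if (!is.null(regions$genes))
    vapply(regions$genes, function(g)
      if (length(g)) paste(g, collapse = ",") else ".", character(1))
  else rep(".", nrow(regions))
  writeLines(paste(regions$contig, format(regions$start, scientific = FALSE,
                                          trim = TRUE),
                   format(regions$end, scientific = FALSE, trim = TRUE),
                   name, sep = "\t"), path)
  invisible(path)
}
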