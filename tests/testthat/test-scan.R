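test_that("site_pi matches the exhaustive pairwise definition", {
  expect_equal(site_pi(2, 4), 4 / 6)       # 4 differing of C(4,2)=6 pairs
  expect_equal(site_pi(0, 10), 0)
  expect_equal(site_pi(1, 2), 1.0)
  # general agreement with the combinatorial formula a(n-a)/C(n,2)
  for (n in c(4, 9, 20)) for (a in 0:n)
    expect_equal(site_pi(a, n), a * (n - a) / choose(n, 2))
  expect_error(site_pi(0, 1), "at least 2")
})

test_that("hudson_fst_site reproduces the plug-in arithmetic", {
  h <- hudson_fst_site(1, 10, 0, 10)
  expect_equal(h$numerator, 1)
  expect_equal(h$denominator, 1)

  h2 <- hudson_fst_site(0.5, 10, 0.5, 10)
  expect_equal(h2$numerator, -0.25 / 9 - 0.25 / 9)
  expect_equal(round(h2$numerator, 5), -0.05556)
  expect_equal(h2$denominator, 0.5)

  h3 <- hudson_fst_site(0.3, 1e9, 0.3, 1e9)
  expect_lt(abs(h3$numerator), 1e-8)
  expect_error(hudson_fst_site(0.5, 1, 0.5, 10), "n >= 2")
})

test_that("make_windows enumerates full windows only", {
  w <- make_windows(c(chr1 = 100000), size = 40000, step = 20000)
  expect_equal(w$start, c(0, 20000, 40000, 60000))
  expect_equal(w$end, w$start + 40000)
  expect_equal(nrow(make_windows(c(chr1 = 39999))), 0)
  tiling <- make_windows(c(chr1 = 100000), size = 20000, step = 20000)
  expect_equal(tiling$start, seq(0, 80000, 20000))
  expect_error(make_windows(c(chr1 = 1e5), size = 100, step = 200), "step")
})

test_that("window_pi and window_fst agree with hand-set brute force", {
  geno <- rbind(c(0L, 1L, 2L), c(1L, 1L, 0L), c(2L, 0L, NA),
                c(0L, 2L, 1L), c(1L, 0L, 0L),
                c(2L, 2L, 2L), c(0L, 0L, 0L), c(1L, 2L, 1L),
                c(2L, 1L, 0L), c(0L, 1L, 2L))
  gm <- toy_gm(geno, populations = rep(c("t", "r"), each = 5),
               pos = c(100L, 250L, 900L))
  win <- list(contig = "chr1", start = 0, end = 1000)
  expect_equal(window_pi(gm, "t", win), brute_window_pi(gm, "t", win))
  expect_equal(window_fst(gm, "t", "r", win),
               brute_window_fst(gm, "t", "r", win))
  # doubling the window length halves per-site diversity
  win2 <- list(contig = "chr1", start = 0, end = 2000)
  expect_equal(window_pi(gm, "t", win2), window_pi(gm, "t", win) / 2)
  # empty window
  win3 <- list(contig = "chr1", start = 1000, end = 2000)
  expect_equal(window_pi(gm, "t", win3), 0)
})

test_that("all sites fixed-different gives window FST of 1", {
  geno <- rbind(matrix(0L, 5, 4), matrix(2L, 5, 4))
  gm <- toy_gm(geno, populations = rep(c("a", "b"), each = 5))
  win <- list(contig = "chr1", start = 0, end = 500)
  expect_equal(window_fst(gm, "a", "b", win), 1)
})

test_that("window statistics match per-window recomputation on simulated data", {
  sim <- small_sim(seed = 12, len = 1.5e5, missing_rate = 0.05)
  w <- make_windows(c(chr1 = 1.5e5), size = 30000, step = 15000)
  st <- window_stats(sim$matrix, "pop1", "pop2", w)
  for (i in seq_len(nrow(st))) {
    win <- list(contig = st$contig[i], start = st$start[i], end = st$end[i])
    expect_equal(st$pi_target[i], window_pi(sim$matrix, "pop1", win))
    expect_equal(st$fst[i], window_fst(sim$matrix, "pop1", "pop2", win))
  }
})

test_that("a single doubly extreme window is the only called region", {
  # background: FST increases with index while the diversity ratio
  # decreases, so the two marginal top-5% sets share only window 40
  n <- 100
  st <- data.frame(contig = "chr1",
                   start = seq(0, by = 20000, length.out = n))
  st$end <- st$start + 40000
  st$n_snps <- 50L
  st$fst <- seq(0.08, 0.12, length.out = n)
  st$pi_target <- rep(0.001, n)
  st$pi_reference <- 0.001 * 2^seq(0.5, -0.5, length.out = n)
  st$fst[40] <- 0.6
  st$pi_reference[40] <- 0.001 * 2^3
  st$pi_ratio <- st$pi_reference / st$pi_target
  st$log2_ratio <- log2(st$pi_ratio)
  called <- call_sweep_regions(st, top_frac = 0.05)
  expect_equal(nrow(called$regions), 1)
  expect_equal(called$regions$start, st$start[40])
  expect_equal(which(called$stats$is_outlier), 40L)
})

test_that("top_frac = 1 flags every defined window, merged per contig", {
  set.seed(34)
  st <- data.frame(contig = rep(c("c1", "c2"), each = 10),
                   start = rep(seq(0, by = 20000, length.out = 10), 2))
  st$end <- st$start + 40000
  st$n_snps <- 10L
  st$fst <- runif(20, 0, 0.3)
  st$pi_target <- runif(20, 5e-4, 2e-3)
  st$pi_reference <- runif(20, 5e-4, 2e-3)
  st$pi_ratio <- st$pi_reference / st$pi_target
  st$log2_ratio <- log2(st$pi_ratio)
  called <- suppressWarnings(call_sweep_regions(st, top_frac = 1))
  expect_true(all(called$stats$is_outlier))
  expect_equal(nrow(called$regions), 2)
  expect_equal(sort(called$regions$contig), c("c1", "c2"))
  expect_equal(called$regions$end - called$regions$start,
               rep(9 * 20000 + 40000, 2))
})

test_that("planted sweeps are recovered across seeds", {
  hits <- vapply(1:6, function(s) {
    sw <- data.frame(contig = "chr1", start = 450001, end = 550000,
                     target_pop = 1, F_sweep = 0.8, diversity_scale = 0.2)
    cfg <- sim_config(n_pops = 2, samples_per_pop = c(6, 20),
                      contigs = c(chr1 = 1e6), F_per_pop = c(0.1, 0.1),
                      sweep_intervals = sw, seed = s + 100)
    sim <- simulate_dataset(cfg)
    st <- window_stats(sim$matrix, "pop1", "pop2",
                       make_windows(c(chr1 = 1e6)))
    r <- call_sweep_regions(st)$regions
    any(r$start < 550000 & r$end > 450000)
  }, logical(1))
  expect_gte(sum(hits), 5)
})

test_that("genes are assigned to regions by span overlap, deduplicated globally", {
  models <- structure(list(
    list(gene_id = "gA", contig = "c1", strand = "+",
         exons = cbind(start = 1000, end = 3000),
         cds = cbind(start = 1000, end = 3000, phase = 0)),
    list(gene_id = "gB", contig = "c1", strand = "-",
         exons = cbind(start = 9500, end = 12000),
         cds = cbind(start = 9500, end = 12000, phase = 0)),
    list(gene_id = "gC", contig = "c2", strand = "+",
         exons = cbind(start = 100, end = 400),
         cds = cbind(start = 100, end = 400, phase = 0))),
    class = "gene_models")
  regions <- data.frame(contig = c("c1", "c1"),
                        start = c(0, 9000), end = c(10000, 15000))
  out <- assign_genes(regions, models)
  expect_equal(out$genes[[1]], c("gA", "gB"))   # gB spans the 10000 boundary
  expect_equal(out$genes[[2]], "gB")
  expect_equal(sort(attr(out, "unique_genes")), c("gA", "gB"))

  empty <- assign_genes(data.frame(contig = "c9", start = 0, end = 100),
                        models)
  expect_length(empty$genes[[1]], 0)
})

test_that("window statistics are invariant under coordinate rescaling", {
  sim <- small_sim(seed = 15, len = 1e5, missing_rate = 0)
  gm2 <- sim$matrix
  gm2$variants$pos <- gm2$variants$pos * 2L
  st1 <- window_stats(sim$matrix, "pop1", "pop2",
                      make_windows(c(chr1 = 1e5), 20000, 10000))
  st2 <- window_stats(gm2, "pop1", "pop2",
                      make_windows(c(chr1 = 2e5), 40000, 20000))
  expect_equal(st2$fst, st1$fst)
  expect_equal(st2$n_snps, st1$n_snps)
  # per-site diversity halves because the window length doubled
  expect_equal(st2$pi_target, st1$pi_target / 2)
})
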