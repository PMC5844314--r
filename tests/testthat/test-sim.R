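test_that("simulation is deterministic: identical seeds give byte-identical files", {
  cfg <- sim_config(n_pops = 2, samples_per_pop = c(5, 5),
                    contigs = c(chr1 = 5e4), F_per_pop = c(0.1, 0.1),
                    seed = 42)
  sim1 <- simulate_dataset(cfg)
  sim2 <- simulate_dataset(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_vcf(sim1$matrix, f1); write_vcf(sim2$matrix, f2)
  expect_identical(readLines(f1), readLines(f2))
  t1 <- tempfile(); t2 <- tempfile()
  write_truth(sim1$truth, t1); write_truth(sim2$truth, t2)
  expect_identical(readLines(t1), readLines(t2))

  models1 <- simulate_gene_models(c(chr1 = 5e4), 4, seed = 3)
  models2 <- simulate_gene_models(c(chr1 = 5e4), 4, seed = 3)
  g1 <- tempfile(); g2 <- tempfile()
  write_gff3(models1, g1); write_gff3(models2, g2)
  expect_identical(readLines(g1), readLines(g2))
})

test_that("missing_rate = 0 yields a fully called matrix; positions increase per contig", {
  sim <- small_sim(seed = 2, missing_rate = 0)
  expect_false(anyNA(sim$matrix$geno))
  v <- sim$matrix$variants
  for (cn in unique(v$contig))
    expect_true(all(diff(v$pos[v$contig == cn]) > 0))
})

test_that("REF/ALT alleles are consistent with the transition flags", {
  sim <- small_sim(seed = 3)
  v <- sim$matrix$variants
  is_ts <- (v$ref == "A" & v$alt == "G") | (v$ref == "G" & v$alt == "A") |
    (v$ref == "C" & v$alt == "T") | (v$ref == "T" & v$alt == "C")
  expect_identical(is_ts, sim$truth$is_transition)
  expect_true(all(v$ref != v$alt))
})

test_that("extreme drift (F = 0.999) nearly fixes both populations at a site", {
  cfg <- sim_config(n_pops = 2, samples_per_pop = c(20, 20),
                    contigs = c(chr1 = 600), snp_density = 1 / 300,
                    F_per_pop = c(0.999, 0.999), missing_rate = 0, seed = 8)
  sim <- simulate_dataset(cfg)
  ac1 <- allele_counts(sim$matrix, pop_rows(sim$matrix, "pop1"))
  ac2 <- allele_counts(sim$matrix, pop_rows(sim$matrix, "pop2"))
  p1 <- ac1$alt / ac1$n
  p2 <- ac2$alt / ac2$n
  expect_true(all(pmin(p1, 1 - p1) < 0.1))
  expect_true(all(pmin(p2, 1 - p2) < 0.1))
})

test_that("empirical population frequencies converge to the truth at n = 200", {
  mean_abs_err <- function(n) {
    cfg <- sim_config(n_pops = 2, samples_per_pop = c(n, n),
                      contigs = c(chr1 = 6e4), F_per_pop = c(0.1, 0.1),
                      missing_rate = 0, seed = 5)
    sim <- simulate_dataset(cfg)
    errs <- vapply(1:2, function(k) {
      ac <- allele_counts(sim$matrix, pop_rows(sim$matrix, paste0("pop", k)))
      mean(abs(ac$alt / ac$n - sim$truth$pop_freqs[, k]))
    }, numeric(1))
    max(errs)
  }
  err200 <- mean_abs_err(200)
  expect_lt(err200, 0.03)
  # the error shrinks with sample size
  expect_lt(err200, mean_abs_err(20))
})

test_that("the transition fraction recovers the configured Ts/Tv bias", {
  cfg <- sim_config(n_pops = 1, samples_per_pop = 2, contigs = c(chr1 = 3e6),
                    F_per_pop = 0.1, snp_density = 1 / 250,
                    tstv_ratio = 2.0, seed = 6)
  sim <- simulate_dataset(cfg)
  n <- length(sim$truth$is_transition)
  expect_gt(n, 10000)
  frac <- mean(sim$truth$is_transition)
  expected <- 2 / 3
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), 4 * se)
  tt <- ts_tv_counts(sim$matrix)
  expect_lt(abs(tt$ratio - 2.0), 0.1)
})

test_that("sweep windows show elevated FST and depressed target diversity", {
  deltas <- t(sapply(1:10, function(s) {
    sw <- data.frame(contig = "chr1", start = 80001, end = 140000,
                     target_pop = 1, F_sweep = 0.8, diversity_scale = 0.2)
    cfg <- sim_config(n_pops = 2, samples_per_pop = c(6, 20),
                      contigs = c(chr1 = 3e5), F_per_pop = c(0.1, 0.1),
                      sweep_intervals = sw, seed = s)
    sim <- simulate_dataset(cfg)
    st <- window_stats(sim$matrix, "pop1", "pop2",
                       make_windows(c(chr1 = 3e5)))
    in_sw <- st$start < 140000 & st$end > 80000
    c(fst = mean(st$fst[in_sw], na.rm = TRUE) -
        mean(st$fst[!in_sw], na.rm = TRUE),
      pi = mean(st$pi_target[in_sw], na.rm = TRUE) -
        mean(st$pi_target[!in_sw], na.rm = TRUE))
  }))
  expect_gt(mean(deltas[, "fst"]), 0)
  expect_lt(mean(deltas[, "pi"]), 0)
})

test_that("mean r2 decays with distance when averaged over seeds", {
  curves <- lapply(1:10, function(s) {
    sim <- small_sim(seed = s, len = 1e5, density = 1 / 150,
                     missing_rate = 0, ld_block_scale = 20000)
    decay_curve(sim$matrix, "pop2", max_distance = 50000,
                bin_width = 10000, seed = 1)$mean_r2
  })
  avg <- colMeans(do.call(rbind, curves))
  expect_true(all(diff(avg) <= 1e-3))   # non-increasing up to noise
  expect_gt(avg[1], avg[length(avg)])
})

test_that("gene models are valid: non-overlapping, phased, both strands", {
  models <- simulate_gene_models(c(chr1 = 2e5, chr2 = 2e5), 20, seed = 10)
  expect_length(models, 20)
  expect_setequal(unique(vapply(models, `[[`, character(1), "strand")),
                  c("+", "-"))
  for (cn in c("chr1", "chr2")) {
    on_c <- Filter(function(m) m$contig == cn, models)
    spans <- t(vapply(on_c, function(m)
      range(c(m$exons[, 1], m$exons[, 2])), numeric(2)))
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    if (nrow(spans) > 1)
      expect_true(all(spans[-1, 1] > spans[-nrow(spans), 2]))
  }
  for (m in models) {
    expect_true(nrow(m$exons) >= 1)
    expect_equal(sum(m$cds[, "end"] - m$cds[, "start"] + 1) %% 3, 0)
    expect_true(all(m$cds[, "phase"] %in% 0:2))
  }
  expect_length(simulate_gene_models(c(chr1 = 1e5), 0), 0)
})

test_that("configuration errors are caught", {
  expect_error(sim_config(contigs = c(chr1 = 0)), "zero-length")
  expect_error(sim_config(n_pops = 2, samples_per_pop = c(5, 0),
                          F_per_pop = c(0.1, 0.1)), "positive")
  expect_error(sim_config(F_per_pop = c(0.1, 0.1, 1.5)), "\\(0,1\\)")
  sw <- data.frame(contig = "chr1", start = 1, end = 100, target_pop = 1,
                   F_sweep = 0.05, diversity_scale = 0.5)
  expect_error(sim_config(contigs = c(chr1 = 1e4), sweep_intervals = sw),
               "F_sweep")
  expect_error(simulate_gene_models(c(chr1 = 5e3), 10), "too short")
})

test_that("truth files round-trip through their own reader", {
  sw <- data.frame(contig = "chr1", start = 1000, end = 5000, target_pop = 2,
                   F_sweep = 0.7, diversity_scale = 0.3)
  cfg <- sim_config(n_pops = 2, samples_per_pop = c(4, 4),
                    contigs = c(chr1 = 3e4), F_per_pop = c(0.1, 0.1),
                    sweep_intervals = sw, seed = 13)
  sim <- simulate_dataset(cfg)
  path <- tempfile()
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$ancestral_freqs, signif(sim$truth$ancestral_freqs, 10))
  expect_equal(unname(back$pop_freqs), unname(signif(sim$truth$pop_freqs, 10)))
  expect_identical(back$is_transition, sim$truth$is_transition)
  expect_equal(back$sweep_intervals$start, 1000)
  expect_equal(back$sweep_intervals$F_sweep, 0.7)
})
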