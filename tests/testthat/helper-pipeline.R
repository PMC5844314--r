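# build a small but complete input set in a temporary directory
pipeline_inputs <- function(dir, seed = 11, len = 3e5,
                            n_genes = min(25, len %/% 1e4)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sw <- data.frame(contig = "chr1", start = round(len * 0.3) + 1,
                   end = round(len * 0.45), target_pop = 1,
                   F_sweep = 0.8, diversity_scale = 0.2)
  cfg <- sim_config(n_pops = 3, samples_per_pop = c(6, 20, 4),
                    contigs = c(chr1 = len), F_per_pop = c(0.12, 0.10, 0.25),
                    sweep_intervals = sw, seed = seed)
  sim <- simulate_dataset(cfg)
  write_vcf(sim$matrix, file.path(dir, "sim.vcf"))
  write_population_map(sim$matrix$samples, file.path(dir, "pops.tsv"))
  models <- simulate_gene_models(c(chr1 = len), n_genes, seed = seed + 1)
  write_gff3(models, file.path(dir, "genes.gff3"))
  ref <- simulate_reference(c(chr1 = len), sim$matrix$variants,
                            seed = seed + 2)
  Biostrings::writeXStringSet(ref, file.path(dir, "ref.fa"))
  gids <- vapply(models, `[[`, character(1), "gene_id")
  set.seed(seed + 3)
  tmap <- data.frame(gene = rep(gids, each = 2),
                     term = sample(paste0("T", 1:6), 2 * length(gids),
                                   replace = TRUE))
  write.table(tmap, file.path(dir, "terms.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  list(dir = dir, sim = sim, models = models)
}

demo_config <- function(in_dir, out_dir, seed = 7) {
  pipeline_config(
    vcf = file.path(in_dir, "sim.vcf"),
    population_map = file.path(in_dir, "pops.tsv"),
    out_dir = out_dir,
    gff3 = file.path(in_dir, "genes.gff3"),
    reference_fasta = file.path(in_dir, "ref.fa"),
    term_map_path = file.path(in_dir, "terms.tsv"),
    pop_target = "pop1", pop_reference = "pop2", pop_outgroup = "pop3",
    window_size = 40000, window_step = 20000,
    ld_max_distance = 100000, ld_bin_width = 20000,
    bootstrap_replicates = 10, seed = seed)
}
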