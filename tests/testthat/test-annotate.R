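# hand-built single-transcript gene model
make_gene <- function(gene_id, contig, strand, exons) {
  lens <- exons[, 2] - exons[, 1] + 1
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  phase <- integer(nrow(exons))
  acc <- 0L
  for (i in ord) {
    phase[i] <- (3L - acc %% 3L) %% 3L
    acc <- acc + lens[i]
  }
  structure(list(list(gene_id = gene_id, contig = contig, strand = strand,
                      exons = exons, cds = cbind(exons, phase = phase))),
            class = "gene_models")
}

snp_row <- function(pos, ref, alt, contig = "chr1") {
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

test_that("codon-level classification follows the standard genetic code", {
  # contig: 10 bp pad + CDS ATGGCTTAA + pad
  seq <- paste0(strrep("C", 10), "ATGGCTTAA", strrep("C", 2000))
  ref <- Biostrings::DNAStringSet(seq); names(ref) <- "chr1"
  gene <- make_gene("g1", "chr1", "+", cbind(start = 11, end = 19))

  ann <- classify_variants(rbind(
    snp_row(16, "T", "C"),   # GCT -> GCC, both Ala
    snp_row(15, "C", "T"),   # GCT -> GTT, Ala -> Val
    snp_row(19, "A", "C")),  # TAA -> TAC, stop -> Tyr
    gene, ref)
  expect_equal(ann$category,
               c("exonic_synonymous", "exonic_nonsynonymous",
                 "exonic_stoploss"))
  expect_equal(ann$gene_id, rep("g1", 3))

  # stop gain: TGC (Cys) -> TGA
  seq2 <- paste0(strrep("A", 10), "ATGTGCTAA", strrep("A", 2000))
  ref2 <- Biostrings::DNAStringSet(seq2); names(ref2) <- "chr1"
  ann2 <- classify_variants(snp_row(16, "C", "A"), gene, ref2)
  expect_equal(ann2$category, "exonic_stopgain")
})

test_that("splice-junction SNPs are called within 2 bp inside the intron", {
  seq <- paste0(strrep("C", 10), "ATGGCTCCC", strrep("G", 10), "GCTGCTTAA",
                strrep("C", 2000))
  ref <- Biostrings::DNAStringSet(seq); names(ref) <- "chr1"
  # exon1 11-19, intron 20-29, exon2 30-38 (CDS 18 bp)
  gene <- make_gene("g1", "chr1", "+",
                    cbind(start = c(11, 30), end = c(19, 38)))
  ann <- classify_variants(rbind(
    snp_row(20, "G", "A"),   # junction + 1
    snp_row(21, "G", "A"),   # junction + 2 -> splicing
    snp_row(22, "G", "A"),   # junction + 3 -> intronic
    snp_row(28, "G", "A"),   # 2 bp before downstream junction -> splicing
    snp_row(25, "G", "A")),  # mid-intron
    gene, ref)
  expect_equal(ann$category, c("splicing", "splicing", "intronic",
                               "splicing", "intronic"))
})

test_that("upstream/downstream use 1 kb from the transcript ends, by strand", {
  seq <- strrep("C", 6000)
  substr(seq, 3001, 3009) <- "ATGGCTTAA"
  ref <- Biostrings::DNAStringSet(seq); names(ref) <- "chr1"
  plus <- make_gene("gp", "chr1", "+", cbind(start = 3001, end = 3009))
  ann <- classify_variants(rbind(
    snp_row(2500, "C", "A"),   # 501 bp before start -> upstream
    snp_row(3500, "C", "A"),   # 491 bp after end -> downstream
    snp_row(1500, "C", "A")),  # 1501 bp away -> intergenic
    plus, ref)
  expect_equal(ann$category, c("upstream", "downstream", "intergenic"))

  minus <- make_gene("gm", "chr1", "-", cbind(start = 3001, end = 3009))
  ann2 <- classify_variants(rbind(
    snp_row(3500, "C", "A"),   # 5' side on minus strand -> upstream
    snp_row(2500, "C", "A")),
    minus, ref)
  expect_equal(ann2$category, c("upstream", "downstream"))
})

test_that("a gene and its reverse-complement mirror give identical verdicts", {
  L <- 4000
  set.seed(21)
  pad <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  cds <- "ATGGCTAGCGATTGCAAGTAA"   # 21 bp ORF
  s <- 1001
  e <- s + nchar(cds) - 1
  seq_fwd <- pad
  substr(seq_fwd, s, e) <- cds
  seq_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq_fwd)))
  ref_fwd <- Biostrings::DNAStringSet(seq_fwd); names(ref_fwd) <- "chr1"
  ref_rev <- Biostrings::DNAStringSet(seq_rev); names(ref_rev) <- "chr1"
  g_fwd <- make_gene("gf", "chr1", "+", cbind(start = s, end = e))
  g_rev <- make_gene("gr", "chr1", "-",
                     cbind(start = L - e + 1, end = L - s + 1))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (offset in c(3, 7, 11, 16, 20)) {
    pos <- s + offset
    ref_base <- substr(seq_fwd, pos, pos)
    alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
    v_f <- classify_variants(snp_row(pos, ref_base, alt_base), g_fwd, ref_fwd)
    v_r <- classify_variants(
      snp_row(L - pos + 1, comp[[ref_base]], comp[[alt_base]]),
      g_rev, ref_rev)
    expect_equal(v_r$category, v_f$category,
                 label = paste("mirrored verdict at offset", offset))
  }
})

test_that("a broken CDS (length not divisible by 3) falls back with a warning", {
  seq <- paste0(strrep("C", 10), "ATGGCTTA", strrep("C", 2000))
  ref <- Biostrings::DNAStringSet(seq); names(ref) <- "chr1"
  gene <- make_gene("gbad", "chr1", "+", cbind(start = 11, end = 18))
  expect_warning(ann <- classify_variants(snp_row(12, "T", "C"), gene, ref),
                 "multiple of 3")
  expect_equal(ann$category, "exonic_unresolved")
})

test_that("annotation partitions simulated SNPs: one category each, counts sum", {
  sim <- small_sim(seed = 9, len = 1e5, density = 1 / 200)
  models <- simulate_gene_models(c(chr1 = 1e5), 8, seed = 2)
  ref <- simulate_reference(c(chr1 = 1e5), sim$matrix$variants, seed = 3)
  ann <- classify_variants(sim$matrix, models, ref)
  expect_equal(nrow(ann), ncol(sim$matrix$geno))
  expect_true(all(ann$category %in% sweepscan:::CATEGORY_LEVELS))
  expect_equal(sum(table(ann$category)), nrow(ann))
  # genic categories carry a gene id, intergenic does not
  expect_true(all(is.na(ann$gene_id[ann$category == "intergenic"])))
  expect_true(all(!is.na(ann$gene_id[ann$category != "intergenic"])))
})

test_that("GFF3 round-trips gene models", {
  models <- simulate_gene_models(c(chr1 = 1e5, chr2 = 8e4), 10, seed = 5)
  path <- tempfile(fileext = ".gff3")
  write_gff3(models, path)
  back <- read_gff3(path)
  expect_length(back, length(models))
  for (i in seq_along(models)) {
    expect_equal(back[[i]]$gene_id, models[[i]]$gene_id)
    expect_equal(back[[i]]$contig, models[[i]]$contig)
    expect_equal(back[[i]]$strand, models[[i]]$strand)
    expect_equal(unname(back[[i]]$exons[, "start"]),
                 unname(models[[i]]$exons[, "start"]))
    expect_equal(unname(back[[i]]$cds[, "phase"]),
                 unname(models[[i]]$cds[, "phase"]))
  }
})
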