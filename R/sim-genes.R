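#' Simulate toy gene models
#'
#' Places non-overlapping multi-exon genes on the given contigs, alternating
#' strands.  Every exon is coding (CDS == exons, no UTRs) and the total CDS
#' length is a multiple of 3 with correct per-exon phase, so the models are
#' valid substrates for codon-level annotation.
#'
#' @param contigs named numeric vector of contig lengths in bp.
#' @param n_genes number of genes to place (>= 0).
#' @param seed integer random seed.
#' @param gene_span_range min/max genomic span of a gene in bp.
#' @return A list of gene models (class `gene_models`); each element has
#'   `gene_id`, `contig`, `strand`, and `exons` / `cds` matrices with columns
#'   `start`, `end` (1-based inclusive) plus per-CDS-interval `phase`.
#' @export
simulate_gene_models <- function(contigs, n_genes, seed = 1L,
                                 gene_span_range = c(2400, 7200)) {
  if (n_genes < 0) stop("n_genes must be >= 0")
  set.seed(seed)
  models <- list()
  if (n_genes == 0) return(structure(models, class = "gene_models"))

  # round-robin over contigs; non-overlapping genes scattered across the
  # full contig length by partitioning the leftover space into random gaps
  contig_of_gene <- rep(names(contigs), length.out = n_genes)
  starts <- ends <- integer(n_genes)
  for (cname in names(contigs)) {
    idx <- which(contig_of_gene == cname)
    if (!length(idx)) next
    spans <- sample(seq(gene_span_range[1], gene_span_range[2], by = 3),
                    length(idx), replace = TRUE)
    slack <- contigs[[cname]] - sum(spans)
    if (slack < length(idx) + 1)
      stop("contig '", cname, "' too short to place ", n_genes, " genes")
    gaps <- diff(c(0, sort(sample.int(slack - 1, length(idx)))))
    starts[idx] <- cumsum(gaps) + c(0, cumsum(spans))[seq_along(idx)] + 1
    ends[idx] <- starts[idx] + spans - 1
  }
  for (g in seq_len(n_genes)) {
    cname <- contig_of_gene[g]
    start <- starts[g]
    end <- ends[g]

    n_exons <- sample(1:4, 1)
    exons <- split_exons(start, end, n_exons)
    strand <- if (g %% 2 == 1) "+" else "-"
    # trim so total coding length is a multiple of 3 (trim the 3' end)
    lens <- exons[, 2] - exons[, 1] + 1
    extra <- sum(lens) %% 3
    if (extra > 0) {
      if (strand == "+") exons[nrow(exons), 2] <- exons[nrow(exons), 2] - extra
      else exons[1, 1] <- exons[1, 1] + extra
    }
    lens <- exons[, 2] - exons[, 1] + 1
    # phase: bases to skip before the first full codon of each CDS interval,
    # accumulated in transcription order
    ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
    phase <- integer(nrow(exons))
    acc <- 0L
    for (i in ord) {
      phase[i] <- (3L - acc %% 3L) %% 3L
      acc <- acc + lens[i]
    }
    models[[g]] <- list(
      gene_id = sprintf("gene%03d", g),
      contig = cname,
      strand = strand,
      exons = exons,
      cds = cbind(exons, phase = phase))
  }
  structure(models, class = "gene_models")
}

split_exons <- function(start, end, n_exons) {
  if (n_exons == 1) return(cbind(start = start, end = end))
  span <- end - start + 1
  # pick internal breakpoints leaving room for >= 60 bp exons and introns
  repeat {
    cuts <- sort(sample(seq(start + 60, end - 60), 2 * (n_exons - 1)))
    ex_start <- c(start, cuts[seq(2, length(cuts), 2)] + 1)
    ex_end <- c(cuts[seq(1, length(cuts), 2)], end)
    if (all(ex_end - ex_start >= 20) &&
        all(ex_start[-1] - ex_end[-n_exons] >= 20)) break
  }
  cbind(start = ex_start, end = ex_end)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x), "genes\n")
  invisible(x)
}

#' Simulate a reference sequence consistent with a variant set
#'
#' Generates random contig sequences and patches the REF allele of every
#' variant in at its position, so that codon lookups around simulated SNPs
#' are consistent with the VCF.
#'
#' @param contigs named numeric vector of contig lengths.
#' @param variants variant table with `contig`, `pos`, `ref` columns (may be
#'   `NULL` for a purely random sequence).
#' @param seed integer random seed.
#' @return A [Biostrings::DNAStringSet] named by contig.
#' @export
simulate_reference <- function(contigs, variants = NULL, seed = 1L) {
  set.seed(seed)
  seqs <- vapply(contigs, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- names(contigs)
  if (!is.null(variants) && nrow(variants)) {
    for (cname in unique(variants$contig)) {
      v <- variants[variants$contig == cname, ]
      at <- IRanges::IRanges(v$pos, width = 1)
      ref[[cname]] <- Biostrings::replaceAt(
        ref[[cname]], at, Biostrings::DNAStringSet(v$ref))
    }
  }
  ref
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features with ID/Parent attributes.
#'
#' @param models a `gene_models` list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    gid <- m$gene_id
    tid <- paste0(gid, ".t1")
    span <- range(c(m$exons[, 1], m$exons[, 2]))
    lines <- c(lines,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              m$contig, span[1], span[2], m$strand, gid),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              m$contig, span[1], span[2], m$strand, tid, gid))
    for (i in seq_len(nrow(m$exons)))
      lines <- c(lines,
        sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                m$contig, m$exons[i, 1], m$exons[i, 2], m$strand, tid))
    for (i in seq_len(nrow(m$cds)))
      lines <- c(lines,
        sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                m$contig, m$cds[i, 1], m$cds[i, 2], m$strand,
                m$cds[i, "phase"], tid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reconstructs the package's gene-model list from a GFF3 file containing
#' gene/mRNA/exon/CDS features (one transcript per gene).
#'
#' @param path GFF3 file path.
#' @return A `gene_models` list, see [simulate_gene_models()].
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", ]
  models <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tx <- df[df$type == "mRNA" & vapply(df$Parent, function(p)
      gid %in% p, logical(1)), ]
    tid <- tx$ID[1]
    is_child <- vapply(df$Parent, function(p) tid %in% p, logical(1))
    ex <- df[df$type == "exon" & is_child, ]
    cds <- df[df$type == "CDS" & is_child, ]
    ex <- ex[order(ex$start), ]
    cds <- cds[order(cds$start), ]
    models[[i]] <- list(
      gene_id = gid,
      contig = as.character(genes$seqnames[i]),
      strand = as.character(genes$strand[i]),
      exons = cbind(start = ex$start, end = ex$end),
      cds = cbind(start = cds$start, end = cds$end,
                  phase = as.integer(as.character(cds$phase))))
  }
  structure(models, class = "gene_models")
}
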