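#' Functional annotation categories
#'
#' Category precedence, most severe first.  A SNP hitting several features
#' (or several genes) receives the single most severe category.
#' @keywords internal
CATEGORY_LEVELS <- c("exonic_stopgain", "exonic_stoploss",
                     "exonic_nonsynonymous", "exonic_synonymous",
                     "exonic_unresolved", "splicing", "intronic",
                     "upstream", "downstream", "intergenic")

#' Classify SNPs against gene models
#'
#' Assigns exactly one annotation category per SNP:
#' * coding (CDS overlap): synonymous / nonsynonymous / stop-gain /
#'   stop-loss, by translating the REF and ALT codons with the standard
#'   genetic code (reverse-complemented on the minus strand);
#' * `splicing`: within 2 bp of an exon-intron junction, on the intron side;
#' * `intronic`;
#' * `upstream` / `downstream`: within 1 kb of the transcript start / end,
#'   respecting strand;
#' * `intergenic` otherwise.
#'
#' When a SNP hits several transcripts the most severe category wins
#' (coding > splicing > intronic > upstream/downstream > intergenic).
#' A gene whose CDS length is not a multiple of 3 cannot be translated; its
#' coding SNPs are reported as `exonic_unresolved` with a warning.
#'
#' @param gm a [geno_matrix()] (or a variant data frame with `contig`,
#'   `pos`, `ref`, `alt`).
#' @param models a `gene_models` list ([simulate_gene_models()] /
#'   [read_gff3()]).
#' @param ref a [Biostrings::DNAStringSet] of contig sequences named by
#'   contig; required to translate coding SNPs (see [simulate_reference()]).
#' @return A data frame: `contig`, `pos`, `ref`, `alt`, `category`,
#'   `gene_id` (`NA` for intergenic).
#' @export
classify_variants <- function(gm, models, ref) {
  v <- if (inherits(gm, "geno_matrix")) gm$variants else as.data.frame(gm)
  n <- nrow(v)
  cat_rank <- rep(length(CATEGORY_LEVELS), n)   # start at intergenic
  gene_id <- rep(NA_character_, n)

  assign_if_better <- function(idx, rank, gid) {
    better <- rank < cat_rank[idx]
    cat_rank[idx[better]] <<- rank
    gene_id[idx[better]] <<- gid
  }

  for (m in models) {
    on_contig <- which(v$contig == m$contig)
    if (!length(on_contig)) next
    pos <- v$pos[on_contig]
    span <- range(c(m$exons[, 1], m$exons[, 2]))

    # coding SNPs
    broken <- sum(m$cds[, "end"] - m$cds[, "start"] + 1) %% 3 != 0
    if (broken)
      warning("gene ", m$gene_id, ": CDS length not a multiple of 3; ",
              "coding SNPs reported as exonic_unresolved")
    in_cds <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(m$cds)))
      in_cds <- in_cds | (pos >= m$cds[i, "start"] & pos <= m$cds[i, "end"])
    for (j in which(in_cds)) {
      k <- on_contig[j]
      cat <- if (broken) "exonic_unresolved"
             else coding_effect(v$pos[k], v$ref[k], v$alt[k], m,
                                ref[[m$contig]])
      assign_if_better(k, match(cat, CATEGORY_LEVELS), m$gene_id)
    }

    # splicing: first/last 2 bp of each intron
    if (nrow(m$exons) > 1) {
      spl <- rep(FALSE, length(pos))
      intr <- rep(FALSE, length(pos))
      for (i in seq_len(nrow(m$exons) - 1)) {
        i_start <- m$exons[i, 2] + 1
        i_end <- m$exons[i + 1, 1] - 1
        if (i_start > i_end) next
        in_intron <- pos >= i_start & pos <= i_end
        intr <- intr | in_intron
        spl <- spl | (in_intron &
                        (pos <= i_start + 1 | pos >= i_end - 1))
      }
      assign_if_better(on_contig[spl], match("splicing", CATEGORY_LEVELS),
                       m$gene_id)
      assign_if_better(on_contig[intr], match("intronic", CATEGORY_LEVELS),
                       m$gene_id)
    }

    # up/downstream within 1 kb of the transcript boundaries, by strand
    five_prime <- if (m$strand == "+") span[1] else span[2]
    three_prime <- if (m$strand == "+") span[2] else span[1]
    up <- if (m$strand == "+")
      pos >= five_prime - 1000 & pos < span[1]
    else pos <= five_prime + 1000 & pos > span[2]
    down <- if (m$strand == "+")
      pos <= three_prime + 1000 & pos > span[2]
    else pos >= three_prime - 1000 & pos < span[1]
    assign_if_better(on_contig[up], match("upstream", CATEGORY_LEVELS),
                     m$gene_id)
    assign_if_better(on_contig[down], match("downstream", CATEGORY_LEVELS),
                     m$gene_id)
  }
  data.frame(contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
             category = CATEGORY_LEVELS[cat_rank], gene_id = gene_id,
             stringsAsFactors = FALSE)
}

# Codon-level effect of a single-base substitution inside a gene's CDS.
coding_effect <- function(pos, ref_allele, alt_allele, model, contig_seq) {
  cds <- model$cds[order(model$cds[, "start"]), , drop = FALSE]
  pieces <- Biostrings::DNAStringSet(Biostrings::extractAt(
    contig_seq, IRanges::IRanges(cds[, "start"], cds[, "end"])))
  cds_seq <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  # genomic offset of pos within the concatenated CDS
  offset <- 0L
  for (i in seq_len(nrow(cds))) {
    if (pos >= cds[i, "start"] && pos <= cds[i, "end"]) {
      offset <- offset + (pos - cds[i, "start"] + 1L)
      break
    }
    offset <- offset + (cds[i, "end"] - cds[i, "start"] + 1L)
  }
  L <- length(cds_seq)
  if (model$strand == "-") {
    cds_seq <- Biostrings::reverseComplement(cds_seq)
    offset <- L - offset + 1L
    ref_allele <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(ref_allele)))
    alt_allele <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(alt_allele)))
  }
  codon_idx <- (offset - 1L) %/% 3L
  within <- offset - 3L * codon_idx
  codon <- as.character(cds_seq[(3L * codon_idx + 1L):(3L * codon_idx + 3L)])
  ref_codon <- codon
  substr(ref_codon, within, within) <- ref_allele
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_allele
  aa_ref <- Biostrings::GENETIC_CODE[[ref_codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (aa_ref == aa_alt) "exonic_synonymous"
  else if (aa_alt == "*") "exonic_stopgain"
  else if (aa_ref == "*") "exonic_stoploss"
  else "exonic_nonsynonymous"
}

#' Transition / transversion accounting
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine substitutions
#' (A<->G, C<->T); all other single-base changes are transversions.
#'
#' @param x a [geno_matrix()], or a data frame / list with `ref` and `alt`
#'   character vectors of single bases.
#' @return A list with `n_transitions`, `n_transversions` and `ratio`
#'   (`NA` when there are no transversions).
#' @export
ts_tv_counts <- function(x) {
  v <- if (inherits(x, "geno_matrix")) x$variants else x
  if (any(nchar(v$ref) != 1L | nchar(v$alt) != 1L))
    stop("ts_tv_counts expects single-base SNP records")
  is_ts <- (v$ref == "A" & v$alt == "G") | (v$ref == "G" & v$alt == "A") |
           (v$ref == "C" & v$alt == "T") | (v$ref == "T" & v$alt == "C")
  n_ts <- sum(is_ts)
  n_tv <- sum(!is_ts)
  list(n_transitions = n_ts, n_transversions = n_tv,
       ratio = tstv_ratio(n_ts, n_tv))
}

#' @rdname ts_tv_counts
#' @param n_ts,n_tv transition and transversion counts.
#' @export
tstv_ratio <- function(n_ts, n_tv) {
  if (n_tv == 0) return(NA_real_)
  n_ts / n_tv
}

#' Write an annotation table as TSV
#' @param ann output of [classify_variants()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
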