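#' Binomial over-representation test for gene sets
#'
#' For each term with m of the M universe genes annotated to it, the number
#' k of selected genes (out of n selected) falling in the term is compared
#' with Binomial(n, m/M): the reported p-value is the exact upper tail
#' P(X >= k).  Selected genes outside the universe are dropped with a
#' warning.  Benjamini-Hochberg adjusted p-values are appended.
#' A hypergeometric tail (sampling without replacement) is available for
#' comparison via `method = "hypergeometric"`.
#'
#' @param selected_genes character vector of selected gene ids.
#' @param term_map a `term_map` from [term_map()] or [read_term_map()].
#' @param method `"binomial"` (default) or `"hypergeometric"`.
#' @return Data frame sorted by p-value: `term_id`, `k`, `n`, `m`, `M`,
#'   `p_value`, `fdr_adjusted_p`; zero rows (with a warning) when no
#'   selected gene is in the universe.
#' @export
binomial_enrichment <- function(selected_genes, term_map,
                                method = c("binomial", "hypergeometric")) {
  method <- match.arg(method)
  stopifnot(inherits(term_map, "term_map"))
  universe <- term_map$universe
  outside <- setdiff(selected_genes, universe)
  if (length(outside))
    warning(length(outside), " selected gene(s) not in the universe dropped")
  sel <- unique(intersect(selected_genes, universe))
  if (!length(sel)) {
    warning("no selected genes in the universe; empty result")
    return(data.frame(term_id = character(), k = integer(), n = integer(),
                      m = integer(), M = integer(), p_value = numeric(),
                      fdr_adjusted_p = numeric()))
  }
  n <- length(sel)
  M <- length(universe)
  res <- lapply(names(term_map$terms), function(tid) {
    genes <- term_map$terms[[tid]]
    m <- length(genes)
    k <- length(intersect(sel, genes))
    p <- if (method == "binomial")
      stats::pbinom(k - 1, n, m / M, lower.tail = FALSE)
    else
      stats::phyper(k - 1, m, M - m, n, lower.tail = FALSE)
    data.frame(term_id = tid, k = k, n = n, m = m, M = M, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$fdr_adjusted_p <- bh_fdr(res$p_value)
  res <- res[order(res$p_value, res$term_id), ]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' the output is in the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gene-to-term annotation map
#'
#' @param terms named list: term id -> character vector of gene ids.
#' @param universe background gene universe; defaults to the union of all
#'   annotated genes.
#' @return An object of class `term_map`.
#' @export
term_map <- function(terms, universe = NULL) {
  terms <- lapply(terms, unique)
  if (is.null(universe)) universe <- unique(unlist(terms))
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  stray <- setdiff(unlist(terms), universe)
  if (length(stray))
    stop("term genes outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  structure(list(terms = terms, universe = universe), class = "term_map")
}

#' Read a gene-to-term map from a two-column TSV
#'
#' Column 1 = gene id, column 2 = term id (a header line `gene<TAB>term` is
#' tolerated).  The universe defaults to all genes in the file.
#'
#' @param path file path.
#' @param universe optional explicit background universe.
#' @return A `term_map`.
#' @export
read_term_map <- function(path, universe = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (identical(tolower(unlist(df[1, 1:2])), c("gene", "term")))
    df <- df[-1, , drop = FALSE]
  terms <- split(df[[1]], df[[2]])
  if (is.null(universe)) universe <- unique(df[[1]])
  term_map(terms, universe)
}

#' @export
print.term_map <- function(x, ...) {
  cat("term_map:", length(x$terms), "terms over", length(x$universe),
      "genes\n")
  invisible(x)
}

#' Write enrichment results as TSV
#' @param res result table from [binomial_enrichment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(res, path) {
  df <- res
  df$p_value <- signif(df$p_value, 8)
  df$fdr_adjusted_p <- signif(df$fdr_adjusted_p, 8)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
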