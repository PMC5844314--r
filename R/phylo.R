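#' Pairwise p-distance between individuals
#'
#' Allele-sharing distance on unphased diploid dosages:
#' d(i, j) = sum |g_i - g_j| / (2 * number of sites called in both).
#' Identical genotypes give 0; opposite homozygotes at every site give 1.
#' With missing data the distance can violate the triangle inequality; such
#' pairs are reported via a message, not silently accepted.
#'
#' @param gm a [geno_matrix()] with >= 2 samples.
#' @param check_triangle scan for triangle-inequality violations and report
#'   them (default `TRUE`; the bootstrap disables it for speed).
#' @return A symmetric numeric matrix with zero diagonal, entries in [0, 1];
#'   the per-pair comparable-site counts are attached as attribute
#'   `n_sites`.
#' @export
p_distance <- function(gm, check_triangle = TRUE) {
  g <- gm$geno
  n <- nrow(g)
  if (n < 2) stop("p_distance requires at least 2 samples")
  d <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  ns <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- !is.na(g[i, ]) & !is.na(g[j, ])
      m <- sum(both)
      if (m == 0)
        stop("samples '", rownames(g)[i], "' and '", rownames(g)[j],
             "' share no called sites")
      d[i, j] <- d[j, i] <- sum(abs(g[i, both] - g[j, both])) / (2 * m)
      ns[i, j] <- ns[j, i] <- m
    }
  }
  viol <- if (check_triangle) triangle_violations(d) else 0L
  if (viol > 0)
    message(viol, " triple(s) violate the triangle inequality ",
            "(possible with missing data)")
  attr(d, "n_sites") <- ns
  d
}

triangle_violations <- function(d, tol = 1e-12) {
  n <- nrow(d)
  if (n < 3) return(0L)
  viol <- 0L
  for (i in seq_len(n - 2))
    for (j in (i + 1):(n - 1))
      for (k in (j + 1):n)
        if (d[i, j] > d[i, k] + d[k, j] + tol ||
            d[i, k] > d[i, j] + d[j, k] + tol ||
            d[j, k] > d[j, i] + d[i, k] + tol) viol <- viol + 1L
  viol
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration; on additive distances the generating topology
#' and branch lengths are recovered exactly.  Negative branch lengths (a
#' known artefact on noisy distances) are clamped to zero with the deficit
#' transferred to the adjacent edge, and the raw minimum is kept as
#' attribute `min_raw_edge`.
#'
#' @param d symmetric numeric distance matrix (>= 3 taxa, zero diagonal).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining requires >= 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  tree <- ape::nj(d)
  min_raw <- min(tree$edge.length)
  if (min_raw < 0) {
    neg <- which(tree$edge.length < 0)
    for (e in neg) {
      deficit <- tree$edge.length[e]
      tree$edge.length[e] <- 0
      parent <- tree$edge[e, 1]
      sib <- which(tree$edge[, 1] == parent)
      sib <- setdiff(sib, e)
      if (length(sib))
        tree$edge.length[sib[1]] <- max(0, tree$edge.length[sib[1]] + deficit)
    }
  }
  attr(tree, "min_raw_edge") <- min_raw
  tree
}

#' Site-resampling bootstrap supports for the NJ tree
#'
#' Resamples variant columns with replacement, recomputes the p-distance and
#' NJ tree per replicate, and reports for each internal bipartition of the
#' point-estimate tree the percentage of replicates containing it.
#'
#' @param gm a [geno_matrix()] with >= 3 samples and >= 3 variants.
#' @param n_replicates bootstrap replicates (default 1000).
#' @param seed integer seed (resampling is fully reproducible).
#' @return The point-estimate `phylo` tree with integer percentage supports
#'   in `$node.label` (root label empty).
#' @export
bootstrap_supports <- function(gm, n_replicates = 1000, seed = 1L) {
  if (ncol(gm$geno) < 3) stop("need at least 3 usable sites")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  build <- function(g) {
    gm2 <- gm
    gm2$geno <- g
    neighbor_joining(p_distance(gm2, check_triangle = FALSE))
  }
  tree <- suppressMessages(build(gm$geno))
  set.seed(seed)
  counts <- suppressMessages(
    ape::boot.phylo(tree, gm$geno, build, B = n_replicates,
                    quiet = TRUE, trees = FALSE))
  pct <- as.integer(round(100 * counts / n_replicates))
  pct[1] <- NA_integer_   # root "bipartition" is not an internal edge
  tree$node.label <- ifelse(is.na(pct), "", as.character(pct))
  tree
}

#' Write / read a tree in Newick format
#'
#' Branch lengths and integer bootstrap supports (as internal node labels)
#' are preserved through a round trip.
#'
#' @param tree an `ape::phylo`.
#' @param path file path.
#' @return `path` invisibly; `read_newick` returns the `phylo`.
#' @export
to_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname to_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Principal component analysis of a genotype matrix
#'
#' Sites are mean-centred and scaled by sqrt(p(1-p)) with p the sample
#' allele frequency (drift-variance scaling); missing dosages are imputed to
#' the site mean (hence contribute zero after centring); monomorphic sites
#' are dropped.  Eigendecomposition of the samples x samples covariance,
#' with a deterministic sign convention: each component's largest-magnitude
#' coordinate is positive.
#'
#' @param gm a [geno_matrix()] with >= 2 samples and >= 1 polymorphic site.
#' @param n_components number of components to return.
#' @return A list of class `pca_result`: `coords` (samples x components),
#'   `eigenvalues` (all, non-increasing), `var_explained` (fractions for
#'   the returned components), `total_variance`.
#' @export
pca <- function(gm, n_components = 2) {
  g <- gm$geno
  if (nrow(g) < 2) stop("pca requires >= 2 samples")
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all sites are monomorphic")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  x <- sweep(g, 2, 2 * p)
  x[is.na(x)] <- 0
  x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  cv <- tcrossprod(x) / ncol(x)
  eig <- eigen(cv, symmetric = TRUE)
  n_components <- min(n_components, ncol(eig$vectors))
  coords <- eig$vectors[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    i_max <- which.max(abs(coords[, k]))
    if (coords[i_max, k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(g)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  total <- sum(diag(cv))
  structure(list(coords = coords,
                 eigenvalues = eig$values,
                 var_explained = eig$values[seq_len(n_components)] / total,
                 total_variance = total),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$coords), "samples,", ncol(x$coords),
      "components\n")
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Write PCA coordinates as TSV
#' @param res a `pca_result`.
#' @param gm the source [geno_matrix()] (for population labels).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pca <- function(res, gm, path) {
  df <- data.frame(sample = rownames(res$coords),
                   population = gm$samples$population[
                     match(rownames(res$coords), gm$samples$sample)],
                   signif(res$coords, 8), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix in square PHYLIP format
#' @param d distance matrix from [p_distance()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(d, path) {
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i)
               paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
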