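#' First-order gene-gene correlation matrix
#'
#' Pairwise correlation of gene expression vectors across samples. Spearman
#' (average ranks for ties) is the default first-order measure because it is
#' invariant to monotone unit transforms (TPM vs log TPM).
#'
#' @param m An [expr_matrix].
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Symmetric gene x gene correlation matrix with unit diagonal.
#'   Genes that are constant across samples have no defined correlation and
#'   yield `NA` entries.
#' @export
first_order_correlation <- function(m, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 3L) stop("need at least 3 samples")
  if (nrow(m$values) < 2L) stop("need at least 2 genes")
  C <- suppressWarnings(stats::cor(t(m$values), method = method))
  diag(C) <- 1
  C
}

#' Second-order (ALAN) gene-association matrix
#'
#' Two-step association: (1) the first-order Spearman correlation matrix C
#' over all genes; (2) for each gene pair (i, j), the Pearson correlation of
#' the correlation profiles C[i, ] and C[j, ] after removing the self columns
#' i and j from both. Genes with similar whole-transcriptome "behavior" score
#' near 1, opposed behavior near -1. The diagonal is defined as exactly 1.
#'
#' The profile correlations are computed by moment correction from the full
#' cross-product matrix, so the cost is two dense matrix products rather than
#' a double loop; the explicit two-loop form is used as a test oracle.
#'
#' @param m An [expr_matrix] with at least 4 genes and 3 samples.
#' @param method First-order correlation method passed to
#'   [first_order_correlation].
#' @return An object of class `alan_matrix`: list with `values` (symmetric
#'   gene x gene matrix in \[-1, 1\], unit diagonal), `gene_ids`, and
#'   `method_meta`.
#' @export
alan_matrix <- function(m, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "expr_matrix"))
  if (nrow(m$values) < 4L) stop("need at least 4 genes")
  if (ncol(m$values) < 3L) stop("need at least 3 samples")
  constant <- apply(m$values, 1, function(x) length(unique(x)) == 1L)
  if (any(constant)) {
    stop(
      "constant gene(s) across samples: ",
      paste(utils::head(gene_ids(m)[constant], 10), collapse = ", "),
      " (apply filter_zero_genes / a variance filter first)"
    )
  }
  C <- first_order_correlation(m, method)
  A <- profile_correlation(C)
  structure(
    list(
      values = A,
      gene_ids = rownames(C),
      method_meta = list(first_order = method, second_order = "pearson")
    ),
    class = "alan_matrix"
  )
}

# Pearson correlation of rows C[i,] and C[j,] with columns i and j removed
# from both, for all pairs at once. For pair (i, j) over the g-2 retained
# columns the needed moments are full-row sums minus the i-th and j-th
# entries; symmetry of C keeps everything expressible in rowSums and C %*% C.
profile_correlation <- function(C) {
  g <- nrow(C)
  np <- g - 2
  rs <- rowSums(C)
  rs2 <- rowSums(C^2)
  CP <- C %*% C # CP[i,j] = sum_k C[i,k] C[j,k]

  di <- diag(C) # = 1
  # per-pair sums with self columns i, j removed
  Sx <- outer(rs, rep(1, g)) - outer(di, rep(1, g)) - C # Sx[i,j] = rs[i] - C[i,i] - C[i,j]
  Sy <- t(Sx)
  Sxx <- outer(rs2, rep(1, g)) - outer(di^2, rep(1, g)) - C^2
  Syy <- t(Sxx)
  # Sxy[i,j] = CP[i,j] - C[i,i]C[j,i] - C[i,j]C[j,j]
  Sxy <- CP - t(C) * di - C * rep(di, each = g)

  num <- np * Sxy - Sx * Sy
  den <- sqrt(pmax(np * Sxx - Sx^2, 0)) * sqrt(pmax(np * Syy - Sy^2, 0))
  A <- num / den
  A[!is.finite(A)] <- NA_real_
  A <- (A + t(A)) / 2 # symmetrize away float noise
  A[A > 1] <- 1
  A[A < -1] <- -1
  diag(A) <- 1
  dimnames(A) <- dimnames(C)
  A
}

#' @export
print.alan_matrix <- function(x, ...) {
  cat("<alan_matrix> ", length(x$gene_ids), " genes; first-order ",
    x$method_meta$first_order, ", second-order ", x$method_meta$second_order,
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Association profile of one gene
#'
#' The gene's row of a square association matrix with the self entry removed:
#' its "behavior" vector against all other genes.
#'
#' @param a An `alan_matrix` or a square named numeric matrix (so first-order
#'   correlation matrices can be profiled the same way).
#' @param gene Gene id.
#' @return Named numeric vector of length `n_genes - 1`.
#' @export
alan_profile <- function(a, gene) {
  vals <- if (inherits(a, "alan_matrix")) a$values else a
  if (!gene %in% rownames(vals)) stop("unknown gene: ", gene)
  p <- vals[gene, ]
  p[setdiff(names(p), gene)]
}

#' Hierarchical clustering of genes (by association) or samples (by z-scored
#' expression)
#'
#' In `"genes"` mode the input is a symmetric similarity matrix in \[-1, 1\]
#' (e.g. an ALAN matrix); distance is `1 - similarity` with average linkage.
#' In `"samples"` mode the input is an expression matrix; genes are z-scored
#' across samples and samples are clustered on Euclidean distance, again with
#' average linkage. Leaf order is deterministic: input rows are taken in
#' gene-id (or sample-id) order before linkage, so ties break by id.
#'
#' @param x Similarity matrix (genes mode) or [expr_matrix] (samples mode).
#' @param on `"genes"` or `"samples"`.
#' @param tol Symmetry tolerance for genes mode.
#' @return List with `hclust` (the tree), `order` (leaf labels in dendrogram
#'   order), and `cut(k)` returning a named cluster labeling.
#' @export
cluster_hierarchical <- function(x, on = c("genes", "samples"), tol = 1e-8) {
  on <- match.arg(on)
  if (on == "genes") {
    vals <- if (inherits(x, "alan_matrix")) x$values else x
    if (!is.matrix(vals) || nrow(vals) != ncol(vals)) stop("genes mode needs a square matrix")
    if (max(abs(vals - t(vals))) > tol) stop("similarity matrix is not symmetric")
    ord <- order(rownames(vals))
    vals <- vals[ord, ord, drop = FALSE]
    if (nrow(vals) == 1L) {
      lab <- rownames(vals)
      return(list(
        hclust = NULL, order = lab,
        cut = function(k) stats::setNames(1L, lab)
      ))
    }
    d <- stats::as.dist(1 - vals)
  } else {
    stopifnot(inherits(x, "expr_matrix"))
    z <- t(scale(t(x$values))) # z-score each gene across samples
    z <- z[apply(is.finite(z), 1, all), , drop = FALSE]
    if (!nrow(z)) stop("no non-constant genes to cluster on")
    m <- t(z)[order(sample_ids(x)), , drop = FALSE]
    d <- stats::dist(m)
  }
  hc <- stats::hclust(d, method = "average")
  list(
    hclust = hc,
    order = hc$labels[hc$order],
    cut = function(k) stats::cutree(hc, k = k)
  )
}

#' 2D embedding of ALAN profiles
#'
#' Runs UMAP (default parameters) on the rows of the association matrix, so
#' genes with similar whole-transcriptome behavior land near each other.
#' Deterministic for a given seed.
#'
#' @param a An `alan_matrix`.
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighborhood size; capped at `n_genes - 1`.
#' @return Data frame with columns `gene_id`, `x`, `y`.
#' @export
embed_profiles <- function(a, seed = 17L, n_neighbors = 15L) {
  stopifnot(inherits(a, "alan_matrix"))
  g <- length(a$gene_ids)
  if (g < 10L) stop("need at least 10 genes to embed")
  set.seed(seed)
  coords <- uwot::umap(
    a$values,
    n_neighbors = min(n_neighbors, g - 1L),
    n_threads = 1, n_sgd_threads = 1
  )
  data.frame(
    gene_id = a$gene_ids,
    x = coords[, 1], y = coords[, 2],
    stringsAsFactors = FALSE
  )
}

#' Coalescence score of a gene set
#'
#' Mean off-diagonal association among the set members: a scalar summary of
#' how strongly a module's genes "move together" in a cohort. Values near 1
#' indicate coalescent behavior, near 0 independence.
#'
#' @param a An `alan_matrix`.
#' @param gene_set Character vector of gene ids; at least 2 must be present.
#' @return A number in \[-1, 1\].
#' @export
coalescence_score <- function(a, gene_set) {
  stopifnot(inherits(a, "alan_matrix"))
  found <- intersect(gene_set, a$gene_ids)
  if (length(found) < 2L) stop("fewer than 2 set genes present in the association matrix")
  sub <- a$values[found, found]
  mean(sub[upper.tri(sub)])
}

#' Write an association matrix, profile, or embedding to TSV
#'
#' @param a An `alan_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alan <- function(a, path) {
  stopifnot(inherits(a, "alan_matrix"))
  df <- data.frame(gene_id = a$gene_ids, a$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
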