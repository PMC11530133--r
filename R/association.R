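#' Correlation between two numeric vectors
#'
#' Spearman (average ranks) or Pearson correlation with a two-sided p-value.
#' The BH-adjusted q is left `NA`; adjustment is applied per analysis family
#' (e.g. one correlation matrix), never per single test.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @param method `"spearman"` or `"pearson"`.
#' @param x_name,y_name Labels recorded on the result.
#' @return One-row `data.frame`: `x_name`, `y_name`, `r`, `p`, `q`, `method`,
#'   `n`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson"),
                      x_name = "x", y_name = "y") {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided", exact = FALSE)
  )
  data.frame(
    x_name = x_name, y_name = y_name,
    r = unname(ct$estimate), p = ct$p.value, q = NA_real_,
    method = method, n = length(x),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.
#' Applied within one analysis family.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Gene-gene correlation matrices, optionally per biopsy-site stratum
#'
#' For the requested genes, computes all pairwise correlations within each
#' stratum (or one stratum, `"all"`, when `strata` is NULL) and BH-adjusts the
#' upper-triangle p-values within each stratum's matrix. Strata with fewer
#' than 3 samples are skipped with a warning.
#'
#' @param m An [expr_matrix].
#' @param genes Character vector of gene ids; all must be present.
#' @param method `"spearman"` (default, as used for hormone-receptor panels)
#'   or `"pearson"`.
#' @param strata Optional named vector mapping sample ids to stratum labels
#'   (e.g. biopsy site).
#' @return Named list per stratum, each with `r` (gene x gene correlation
#'   matrix) and `tests` (long data.frame of upper-triangle pairs with `r`,
#'   `p`, `q`).
#' @export
correlation_matrix <- function(m, genes, method = c("spearman", "pearson"),
                               strata = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(m, "expr_matrix"))
  absent <- setdiff(genes, gene_ids(m))
  if (length(absent)) stop("gene(s) absent from matrix: ", paste(absent, collapse = ", "))
  if (is.null(strata)) {
    strata <- stats::setNames(rep("all", ncol(m$values)), sample_ids(m))
  }
  strata <- strata[sample_ids(m)]
  out <- list()
  for (lev in unique(as.character(strata))) {
    cols <- which(as.character(strata) == lev)
    if (length(cols) < 3L) {
      warning("stratum '", lev, "' has fewer than 3 samples; skipped")
      next
    }
    sub <- m$values[genes, cols, drop = FALSE]
    tests <- do.call(rbind, apply(
      utils::combn(genes, 2), 2,
      function(pr) {
        correlate(sub[pr[1], ], sub[pr[2], ],
          method = method,
          x_name = pr[1], y_name = pr[2]
        )
      },
      simplify = FALSE
    ))
    tests$q <- bh_adjust(tests$p)
    r <- diag(1, length(genes))
    dimnames(r) <- list(genes, genes)
    for (k in seq_len(nrow(tests))) {
      r[tests$x_name[k], tests$y_name[k]] <- tests$r[k]
      r[tests$y_name[k], tests$x_name[k]] <- tests$r[k]
    }
    out[[lev]] <- list(r = r, tests = tests, n = length(cols))
  }
  if (!length(out)) stop("no stratum with at least 3 samples")
  out
}

#' Two-group comparison tests
#'
#' Thin dispatch over the standard tests used for group contrasts:
#' Mann-Whitney U (exact enumeration when both groups have <= 20 observations
#' and no ties, normal approximation with tie correction otherwise), paired
#' Wilcoxon signed-rank, Welch t, or chi-squared on a contingency table.
#'
#' @param values Numeric vector (or a contingency matrix for `test = "chi2"`).
#' @param labels Two-level grouping of `values` (ignored for `chi2`; defines
#'   pairing order for the paired test).
#' @param test One of `"mannwhitney"`, `"wilcoxon_paired"`, `"ttest"`,
#'   `"chi2"`.
#' @return List with `statistic` and `p`.
#' @export
group_compare <- function(values, labels = NULL,
                          test = c("mannwhitney", "wilcoxon_paired", "ttest", "chi2")) {
  test <- match.arg(test)
  if (test == "chi2") {
    if (!is.matrix(values)) stop("chi2 expects a contingency matrix")
    ht <- suppressWarnings(stats::chisq.test(values, correct = FALSE))
    return(list(statistic = unname(ht$statistic), p = ht$p.value))
  }
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly 2 levels")
  g1 <- values[labels == levels(labels)[1]]
  g2 <- values[labels == levels(labels)[2]]
  if (length(g1) < (if (test == "mannwhitney") 2L else 2L) || length(g2) < 2L) {
    stop("each group needs at least 2 observations")
  }
  ht <- switch(test,
    mannwhitney = {
      exact <- length(g1) <= 20L && length(g2) <= 20L && !anyDuplicated(c(g1, g2))
      suppressWarnings(stats::wilcox.test(g1, g2, exact = exact, correct = TRUE))
    },
    wilcoxon_paired = {
      if (length(g1) != length(g2)) stop("paired test requires matched vectors")
      if (all(g1 == g2)) stop("all paired differences are zero; statistic undefined")
      suppressWarnings(stats::wilcox.test(g1, g2, paired = TRUE))
    },
    ttest = {
      if (stats::sd(g1) == 0 && stats::sd(g2) == 0) {
        stop("degenerate t-test: both groups are constant")
      }
      if (length(g1) == length(g2) && all(g1 == g2)) {
        stop("degenerate t-test: groups are identical")
      }
      stats::t.test(g1, g2)
    }
  )
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Quartile-contrast differential expression
#'
#' Per gene: `logFC = log2((mean TPM in B + 1) / (mean TPM in A + 1))` where B
#' is the second factor level (the "Q4" arm), p from a two-sided Mann-Whitney
#' U test, q by BH over all genes. The significance flag applies
#' `q < q_max & |logFC| > lfc_min` to the stated side. Genes are ranked by the
#' signed score `-log10(q) * sign(logFC)` (logFC as tie-break), rank 1 = most
#' enriched in B — the order of a "snake plot".
#'
#' @param m An [expr_matrix] with `unit = "TPM"`, pre-filtered of all-zero
#'   genes.
#' @param labels Named two-level factor/character over a subset of samples
#'   (e.g. Q1 vs Q4 of a signature score); at least 3 samples per level.
#' @param q_max,lfc_min Significance thresholds (defaults `0.001` and `1.5`).
#' @return `data.frame`: `gene_id`, `logFC`, `p`, `q`, `rank`, `significant`.
#' @export
differential_expression <- function(m, labels, q_max = 0.001, lfc_min = 1.5) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "TPM") stop("differential_expression expects unit 'TPM'")
  labels <- labels[!is.na(labels)]
  if (is.null(names(labels))) stop("labels must be named by sample id")
  labels <- stats::setNames(factor(as.character(labels)), names(labels))
  if (nlevels(labels) != 2L) stop("labels must have exactly 2 levels")
  keep <- intersect(names(labels), sample_ids(m))
  labels <- labels[keep]
  if (min(table(labels)) < 3L) stop("each group needs at least 3 samples")
  grpA <- names(labels)[labels == levels(labels)[1]]
  grpB <- names(labels)[labels == levels(labels)[2]]
  va <- m$values[, grpA, drop = FALSE]
  vb <- m$values[, grpB, drop = FALSE]
  logfc <- log2((rowMeans(vb) + 1) / (rowMeans(va) + 1))
  exact <- length(grpA) <= 20L && length(grpB) <= 20L
  p <- vapply(seq_len(nrow(va)), function(i) {
    suppressWarnings(stats::wilcox.test(vb[i, ], va[i, ], exact = exact)$p.value)
  }, numeric(1))
  q <- bh_adjust(pmax(p, .Machine$double.xmin))
  score <- -log10(q) * sign(logfc)
  ord <- order(-score, -logfc)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  data.frame(
    gene_id = gene_ids(m),
    logFC = logfc, p = p, q = q, rank = rank,
    significant = q < q_max & abs(logfc) > lfc_min,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
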