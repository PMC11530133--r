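#' Sum-of-log signature score
#'
#' Per sample, the sum of `ln(TPM + 1)` over the genes of a set:
#' `score_s = sum_{g in set} ln(TPM_gs + 1)`. Genes missing from the matrix
#' are dropped with a warning listing them.
#'
#' @param m An [expr_matrix] with `unit = "TPM"`.
#' @param gene_set Character vector of gene ids; at least one must be present.
#' @param gene_set_name Label recorded on the result.
#' @return A `score_vector`: list with named numeric `scores`, `kind`
#'   (`"sumlog_raw"`), `gene_set_name`, `scaling_meta`.
#' @export
sumlog_score <- function(m, gene_set, gene_set_name = "signature") {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "TPM") stop("sumlog_score expects unit 'TPM', got '", m$unit, "'")
  found <- intersect(gene_set, gene_ids(m))
  missing <- setdiff(gene_set, found)
  if (!length(found)) stop("no genes of the set are present in the matrix")
  if (length(missing)) {
    warning("set genes absent from matrix: ", paste(missing, collapse = ", "))
  }
  s <- colSums(log1p(m$values[found, , drop = FALSE]))
  score_vector(s, "sumlog_raw", gene_set_name)
}

score_vector <- function(scores, kind, gene_set_name, scaling_meta = NULL) {
  structure(
    list(
      scores = scores, kind = kind,
      gene_set_name = gene_set_name, scaling_meta = scaling_meta
    ),
    class = "score_vector"
  )
}

#' @export
print.score_vector <- function(x, ...) {
  cat("<score_vector> ", length(x$scores), " samples; kind ", x$kind,
    "; set ", x$gene_set_name, "\n",
    sep = ""
  )
  invisible(x)
}

#' Scale scores to the 0-100 range across the cohort
#'
#' `(x - min) / (max - min) * 100`; the cohort minimum maps to exactly 0 and
#' the maximum to exactly 100. Invariant to positive affine transforms of the
#' input and rank-preserving.
#'
#' @param s A `score_vector` with at least two distinct values.
#' @return A `score_vector` of kind `"scaled_0_100"` carrying the original
#'   min/max in `scaling_meta`.
#' @export
scale_0_100 <- function(s) {
  stopifnot(inherits(s, "score_vector"))
  lo <- min(s$scores)
  hi <- max(s$scores)
  if (hi == lo) stop("constant scores cannot be scaled to 0-100")
  score_vector(
    (s$scores - lo) / (hi - lo) * 100,
    "scaled_0_100", s$gene_set_name,
    scaling_meta = list(min = lo, max = hi)
  )
}

#' Mean z-score signature
#'
#' Each gene is z-scored across samples (sd with the n-1 denominator), then
#' the per-sample mean over the set genes is taken. The cohort mean of the
#' resulting score is 0 by construction.
#'
#' @param m An [expr_matrix] (any unit; z-scoring removes per-gene scale).
#' @param gene_set Character vector of gene ids.
#' @param gene_set_name Label recorded on the result.
#' @return A `score_vector` of kind `"mean_z"`; `scaling_meta` holds the
#'   per-gene means and sds.
#' @export
meanz_score <- function(m, gene_set, gene_set_name = "signature") {
  stopifnot(inherits(m, "expr_matrix"))
  found <- intersect(gene_set, gene_ids(m))
  missing <- setdiff(gene_set, found)
  if (!length(found)) stop("no genes of the set are present in the matrix")
  if (length(missing)) {
    warning("set genes absent from matrix: ", paste(missing, collapse = ", "))
  }
  sub <- m$values[found, , drop = FALSE]
  mu <- rowMeans(sub)
  sd <- apply(sub, 1, stats::sd)
  if (any(sd == 0)) {
    stop("constant gene(s) in set: ", paste(found[sd == 0], collapse = ", "))
  }
  z <- (sub - mu) / sd
  score_vector(
    colMeans(z), "mean_z", gene_set_name,
    scaling_meta = list(gene_means = mu, gene_sds = sd)
  )
}

# Type-7 quantile cut with an explicit ambiguity check: samples are HIGH only
# when strictly above the cut, so a cut that lands on a duplicated value makes
# membership depend on arbitrary ordering -> error listing the tied samples.
quantile_cut <- function(scores, p, side) {
  q <- unname(stats::quantile(scores, p, type = 7))
  tied <- names(scores)[scores == q]
  if (length(tied) > 1L) {
    stop(
      "tied scores at the ", side, " cut (", format(q), "): ",
      paste(tied, collapse = ", ")
    )
  }
  q
}

#' Stratify samples into HIGH / LOW / MID by score percentiles
#'
#' HIGH are the samples strictly above the (1 - pct) type-7 quantile, LOW
#' strictly below the pct quantile, the rest MID. With distinct scores this
#' convention yields, e.g., 52 HIGH of 208 samples at pct = 0.25 and 21 at
#' pct = 0.10. Ties sitting exactly on a cut are an error (membership would be
#' arbitrary), listing the offending samples.
#'
#' @param s A `score_vector` (or named numeric vector).
#' @param pct Tail fraction, strictly between 0 and 0.5.
#' @return Named character vector over samples with values
#'   `"HIGH"`, `"LOW"`, `"MID"`.
#' @export
stratify_extremes <- function(s, pct = 0.25) {
  scores <- if (inherits(s, "score_vector")) s$scores else s
  if (is.null(names(scores))) stop("scores must be named by sample id")
  if (!(pct > 0 && pct < 0.5)) stop("pct must be in (0, 0.5)")
  q_hi <- quantile_cut(scores, 1 - pct, "upper")
  q_lo <- quantile_cut(scores, pct, "lower")
  lab <- rep("MID", length(scores))
  lab[scores > q_hi] <- "HIGH"
  lab[scores < q_lo] <- "LOW"
  stats::setNames(lab, names(scores))
}

#' Four-way labels from two signature scores
#'
#' Each score is stratified independently with [stratify_extremes]; a sample
#' is assigned the combination of its two HIGH/LOW calls (e.g.
#' `"APUC6hi_ARlo"`). Samples MID on either score are `"UNASSIGNED"`.
#'
#' @param apuc,ar `score_vector`s (or named numeric vectors) over the same
#'   sample set; the first names the `APUC6` half of the label, the second the
#'   `AR` half.
#' @param pct Tail fraction for both stratifications.
#' @return Named character vector with values in
#'   `{"APUC6hi_ARhi", "APUC6hi_ARlo", "APUC6lo_ARhi", "APUC6lo_ARlo",
#'   "UNASSIGNED"}`.
#' @export
four_group_labels <- function(apuc, ar, pct = 0.25) {
  a <- if (inherits(apuc, "score_vector")) apuc$scores else apuc
  b <- if (inherits(ar, "score_vector")) ar$scores else ar
  if (!setequal(names(a), names(b))) stop("the two scores cover different sample sets")
  b <- b[names(a)]
  la <- stratify_extremes(a, pct)
  lb <- stratify_extremes(b, pct)
  lab <- rep("UNASSIGNED", length(a))
  both <- la != "MID" & lb != "MID"
  code <- function(x, hi, lo) ifelse(x == "HIGH", hi, lo)
  lab[both] <- paste0(
    code(la[both], "APUC6hi", "APUC6lo"), "_",
    code(lb[both], "ARhi", "ARlo")
  )
  stats::setNames(lab, names(a))
}

#' Overlap of two high-score groups at a percentile threshold
#'
#' Counts samples strictly above the (1 - pct) quantile of each score and
#' above both (the Venn intersection used for coexpression counts).
#'
#' @param a,b `score_vector`s (or named numeric vectors) over the same samples.
#' @param pct Tail fraction.
#' @return Named integer vector `c(n_a, n_b, n_both)`.
#' @export
threshold_overlap <- function(a, b, pct = 0.25) {
  x <- if (inherits(a, "score_vector")) a$scores else a
  y <- if (inherits(b, "score_vector")) b$scores else b
  if (!setequal(names(x), names(y))) stop("the two scores cover different sample sets")
  y <- y[names(x)]
  in_a <- x > quantile_cut(x, 1 - pct, "upper")
  in_b <- y > quantile_cut(y, 1 - pct, "upper")
  c(n_a = sum(in_a), n_b = sum(in_b), n_both = sum(in_a & in_b))
}
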