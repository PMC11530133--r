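#' Build a ranked gene list
#'
#' Sorts a named statistic vector in strictly descending order with a
#' deterministic tie-break by gene id. Duplicate genes or non-finite
#' statistics are errors.
#'
#' @param stats Named numeric vector: gene id -> ranking statistic (e.g. a
#'   signed differential-expression score).
#' @return Named numeric vector sorted descending (class `ranked_list`).
#' @export
ranked_list <- function(stats) {
  if (is.null(names(stats))) stop("statistics must be named by gene id")
  if (anyDuplicated(names(stats))) stop("duplicate genes in ranked list")
  if (any(!is.finite(stats))) stop("non-finite ranking statistics")
  out <- stats[order(-stats, names(stats))]
  class(out) <- c("ranked_list", "numeric")
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|stat|^weight / sum_hits |stat|^weight`
#' at set members ("hits") and `-1 / (N - N_hits)` at non-members. ES is the
#' running-sum value of maximal magnitude (sign retained). The leading edge is
#' the hit genes at or before the positive extremum (or at/after the negative
#' extremum for negative ES).
#'
#' @param r A [ranked_list] (or named numeric vector; it is sorted if needed).
#' @param gene_set Character vector; at least one member must be in `r` and
#'   the set must not cover the whole list.
#' @param weight Non-negative exponent on the statistic (classic default 1;
#'   0 gives the unweighted KS statistic).
#' @return List with `ES`, `running` (named numeric, one value per list
#'   position), and `leading_edge`.
#' @export
enrichment_score <- function(r, gene_set, weight = 1) {
  if (!inherits(r, "ranked_list")) r <- ranked_list(r)
  if (weight < 0) stop("weight must be >= 0")
  hits <- names(r) %in% gene_set
  nh <- sum(hits)
  if (nh == 0L) stop("no overlap between gene set and ranked list")
  if (nh == length(r)) stop("gene set covers the entire ranked list")
  w <- abs(r)^weight
  incr <- numeric(length(r))
  denom <- sum(w[hits])
  if (denom == 0) {
    # all hit statistics are exactly zero: fall back to equal hit weights
    incr[hits] <- 1 / nh
  } else {
    incr[hits] <- w[hits] / denom
  }
  incr[!hits] <- -1 / (length(r) - nh)
  running <- cumsum(incr)
  names(running) <- names(r)
  i_ext <- which.max(abs(running))
  es <- running[[i_ext]]
  le <- if (es >= 0) {
    names(r)[seq_len(i_ext)][hits[seq_len(i_ext)]]
  } else {
    idx <- i_ext:length(r)
    names(r)[idx][hits[idx]]
  }
  list(ES = es, running = running, leading_edge = le)
}

# signal-to-noise ranking statistic for phenotype permutation:
# (mean_B - mean_A) / (sd_B + sd_A), the classic two-phenotype metric
signal_to_noise <- function(values, is_b) {
  a <- values[, !is_b, drop = FALSE]
  b <- values[, is_b, drop = FALSE]
  sa <- apply(a, 1, stats::sd)
  sb <- apply(b, 1, stats::sd)
  den <- sa + sb
  den[den == 0] <- .Machine$double.eps
  (rowMeans(b) - rowMeans(a)) / den
}

#' Permutation gene-set enrichment analysis
#'
#' Computes the weighted-KS enrichment score for each set, a permutation null,
#' normalized enrichment scores and permutation FDR. Two null schemes:
#' \describe{
#'   \item{`gene_perm`}{preranked input; each permutation draws a random gene
#'     set of the same size from the list.}
#'   \item{`phenotype_perm`}{`r` is an [expr_matrix] and `labels` a two-level
#'     grouping; each permutation shuffles the sample labels and re-ranks all
#'     genes by the signal-to-noise statistic (second level vs first).}
#' }
#' NES = ES / mean(|permuted ES| of the same sign); FDR for a set is the
#' fraction of same-sign permuted NES at least as extreme, divided by the
#' fraction of same-sign observed NES at least as extreme, capped at 1.
#' Deterministic given `seed`.
#'
#' @param r A [ranked_list] (gene_perm) or [expr_matrix] (phenotype_perm).
#' @param sets Named list of gene-id vectors; sets with no overlap are dropped
#'   with a warning.
#' @param n_perm Number of permutations (>= 100).
#' @param mode `"gene_perm"` or `"phenotype_perm"`.
#' @param labels Two-level sample grouping (phenotype mode only).
#' @param weight Exponent passed to [enrichment_score].
#' @param seed Integer seed.
#' @return `data.frame`: `set_name`, `size`, `ES`, `NES`, `fdr`, `n_perm`,
#'   `leading_edge` (';'-joined).
#' @export
gsea <- function(r, sets, n_perm = 1000L,
                 mode = c("gene_perm", "phenotype_perm"),
                 labels = NULL, weight = 1, seed = 7L) {
  mode <- match.arg(mode)
  if (!length(sets)) stop("empty gene-set collection")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  set.seed(seed)

  if (mode == "phenotype_perm") {
    stopifnot(inherits(r, "expr_matrix"))
    if (is.null(labels)) stop("phenotype_perm requires sample labels")
    labels <- labels[sample_ids(r)]
    labels <- if (is.factor(labels)) droplevels(labels) else factor(as.character(labels))
    if (nlevels(labels) != 2L) stop("labels must have exactly 2 levels")
    is_b <- labels == levels(labels)[2]
    obs_rank <- ranked_list(signal_to_noise(r$values, is_b))
  } else {
    obs_rank <- if (inherits(r, "ranked_list")) r else ranked_list(r)
  }

  keep <- vapply(sets, function(s) any(names(obs_rank) %in% s), logical(1))
  if (!any(keep)) stop("no gene set overlaps the ranked list")
  if (any(!keep)) {
    warning("dropping set(s) with no overlap: ", paste(names(sets)[!keep], collapse = ", "))
  }
  sets <- sets[keep]

  obs <- lapply(sets, function(s) enrichment_score(obs_rank, s, weight))
  es_obs <- vapply(obs, `[[`, numeric(1), "ES")
  sizes <- vapply(sets, function(s) sum(names(obs_rank) %in% s), integer(1))

  # permutation ES: sets x n_perm
  es_perm <- matrix(NA_real_, nrow = length(sets), ncol = n_perm)
  if (mode == "gene_perm") {
    gene_pool <- names(obs_rank)
    for (b in seq_len(n_perm)) {
      for (k in seq_along(sets)) {
        rs <- sample(gene_pool, sizes[k])
        es_perm[k, b] <- enrichment_score(obs_rank, rs, weight)$ES
      }
    }
  } else {
    for (b in seq_len(n_perm)) {
      perm_b <- sample(is_b)
      rk <- ranked_list(signal_to_noise(r$values, perm_b))
      for (k in seq_along(sets)) {
        es_perm[k, b] <- enrichment_score(rk, sets[[k]], weight)$ES
      }
    }
  }

  nes_of <- function(es, null_es) {
    pos <- null_es[null_es > 0]
    neg <- null_es[null_es < 0]
    if (es >= 0) {
      m <- if (length(pos)) mean(pos) else NA_real_
      es / m
    } else {
      m <- if (length(neg)) mean(abs(neg)) else NA_real_
      es / m
    }
  }
  nes_obs <- vapply(seq_along(sets), function(k) nes_of(es_obs[k], es_perm[k, ]), numeric(1))
  nes_perm <- matrix(NA_real_, nrow = length(sets), ncol = n_perm)
  for (k in seq_along(sets)) {
    nes_perm[k, ] <- vapply(es_perm[k, ], function(e) nes_of(e, es_perm[k, ]), numeric(1))
  }

  fdr <- vapply(seq_along(sets), function(k) {
    nes <- nes_obs[k]
    if (!is.finite(nes)) {
      return(NA_real_)
    }
    if (nes >= 0) {
      null_pool <- nes_perm[nes_perm >= 0 & is.finite(nes_perm)]
      obs_pool <- nes_obs[nes_obs >= 0 & is.finite(nes_obs)]
      num <- mean(null_pool >= nes)
      den <- mean(obs_pool >= nes)
    } else {
      null_pool <- nes_perm[nes_perm < 0 & is.finite(nes_perm)]
      obs_pool <- nes_obs[nes_obs < 0 & is.finite(nes_obs)]
      num <- mean(null_pool <= nes)
      den <- mean(obs_pool <= nes)
    }
    min(1, if (den > 0) num / den else 1)
  }, numeric(1))

  data.frame(
    set_name = names(sets),
    size = sizes,
    ES = unname(es_obs),
    NES = unname(nes_obs),
    fdr = fdr,
    n_perm = n_perm,
    leading_edge = vapply(obs, function(o) paste(o$leading_edge, collapse = ";"), character(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
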