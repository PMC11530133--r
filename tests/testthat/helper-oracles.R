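# Independent oracles and fixture builders shared across tests.

# Explicit two-loop ALAN reference: ranks -> Spearman matrix -> Pearson of
# profiles with self columns removed. Deliberately naive.
alan_oracle <- function(vals) {
  C <- stats::cor(t(vals), method = "spearman")
  diag(C) <- 1
  g <- nrow(C)
  A <- diag(1, g)
  dimnames(A) <- dimnames(C)
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      if (i != j) {
        keep <- setdiff(seq_len(g), c(i, j))
        A[i, j] <- stats::cor(C[i, keep], C[j, keep])
      }
    }
  }
  A
}

# Exact two-sided Mann-Whitney p by enumeration of all label assignments.
mw_enum_oracle <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  u_of <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Cumulative running-sum ES oracle (independent of enrichment_score).
es_oracle <- function(stats_sorted, set, weight = 1) {
  hit <- names(stats_sorted) %in% set
  w <- abs(stats_sorted)^weight
  step <- ifelse(hit, w / sum(w[hit]), -1 / sum(!hit))
  run <- cumsum(step)
  run[which.max(abs(run))]
}

# Random non-constant expression fixture (genes x samples).
random_expr <- function(g, n, seed, unit = "counts") {
  set.seed(seed)
  v <- matrix(
    abs(rnorm(g * n, mean = 5)), g, n,
    dimnames = list(paste0("g", seq_len(g)), paste0("s", seq_len(n)))
  )
  expr_matrix(v, unit)
}

# Wrap a named numeric vector as a raw score_vector.
score_vector_for_test <- function(x) {
  apucnet:::score_vector(x, "sumlog_raw", "test")
}

# Named score vector with distinct values in random order.
distinct_scores <- function(n, seed) {
  set.seed(seed)
  stats::setNames(sample(seq_len(n) + stats::runif(n, 0, 0.4)), paste0("p", seq_len(n)))
}
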