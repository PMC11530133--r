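test_that("correlate matches textbook hand-rank Spearman and handles extremes", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 0.1)
  y <- c(2, 0.5, 5, 1, 8, 3, 6, 5.5, 11, 0.2)
  # hand computation: Pearson correlation of the rank vectors
  hand <- stats::cor(rank(x), rank(y))
  res <- correlate(x, y, "spearman")
  expect_equal(res$r, hand, tolerance = 1e-12)
  expect_equal(correlate(x, x, "pearson")$r, 1)
  expect_equal(correlate(x, -x, "pearson")$r, -1)
  expect_equal(correlate(x, -x, "spearman")$r, -1)
  expect_error(correlate(x, rep(1, 10)), "constant")
  expect_error(correlate(x, y[-1]), "equal length")
})

test_that("Spearman correlation is invariant under monotone transforms", {
  set.seed(30)
  x <- rnorm(25)
  y <- x + rnorm(25)
  r0 <- correlate(x, y, "spearman")$r
  expect_equal(correlate(exp(x), y, "spearman")$r, r0)
  expect_equal(correlate(x, y^3 + 5, "spearman")$r, r0)
})

test_that("BH adjustment matches the hand step-up example and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.005, 0.9, 0.04, 0.2, 0.011)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  shuf <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p[shuf]), q[shuf])
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("correlation_matrix adjusts within stratum and skips tiny strata", {
  m <- random_expr(3, 30, seed = 31)
  res <- correlation_matrix(m, c("g1", "g2", "g3"), "spearman")
  expect_named(res, "all")
  expect_equal(nrow(res$all$tests), 3L) # upper triangle of 3 genes
  expect_equal(res$all$tests$q, bh_adjust(res$all$tests$p))
  expect_equal(res$all$r, t(res$all$r))

  strata <- stats::setNames(
    rep(c("bone", "tiny"), c(28, 2)), sample_ids(m)
  )
  expect_warning(res2 <- correlation_matrix(m, c("g1", "g2"), strata = strata), "tiny")
  expect_named(res2, "bone")
  expect_error(correlation_matrix(m, c("g1", "nope")), "nope")
})

test_that("planted module/SHR structure shows up in the stratified correlation matrix", {
  cfg <- sim_config(
    n_samples = c(benign = 30, primary = 30, metastatic = 400),
    module_rho = c(benign = 0.1, primary = 0.4, metastatic = 0.7),
    shr_rho = 0.5, seed = 32
  )
  m <- generate_expression(cfg, "metastatic")
  genes <- c(cfg$module_genes, cfg$shr_genes, "AR")
  res <- correlation_matrix(m, genes, "spearman")
  tests <- res$all$tests
  is_mod_shr <- (tests$x_name %in% cfg$module_genes & tests$y_name %in% cfg$shr_genes) |
    (tests$y_name %in% cfg$module_genes & tests$x_name %in% cfg$shr_genes)
  expect_true(all(tests$r[is_mod_shr] > 0))
  expect_true(all(tests$q[is_mod_shr] < 0.05))
  is_mod_ar <- xor(tests$x_name == "AR", tests$y_name == "AR") &
    (tests$x_name %in% cfg$module_genes | tests$y_name %in% cfg$module_genes)
  expect_true(all(abs(tests$r[is_mod_ar]) < 0.25))
})

test_that("Mann-Whitney exact path equals full enumeration for small groups", {
  res <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3), "mannwhitney")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1)
  set.seed(33)
  for (k in 1:8) {
    n1 <- sample(2:7, 1)
    n2 <- sample(2:7, 1)
    g1 <- rnorm(n1)
    g2 <- rnorm(n2, 0.8)
    res <- group_compare(c(g1, g2), rep(c("a", "b"), c(n1, n2)), "mannwhitney")
    expect_equal(res$p, mw_enum_oracle(g1, g2), tolerance = 1e-12)
  }
})

test_that("chi2, paired wilcoxon, and t-test dispatch behave on their contracts", {
  tab <- matrix(c(10, 20, 10, 20), 2, 2)
  expect_equal(group_compare(tab, test = "chi2")$statistic, 0)
  expect_error(
    group_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3), "ttest"),
    "identical"
  )
  expect_error(
    group_compare(rep(1, 6), rep(c("a", "b"), each = 3), "wilcoxon_paired"),
    "zero"
  )
  set.seed(34)
  x <- rnorm(12)
  res <- group_compare(c(x, x + 2), rep(c("a", "b"), each = 12), "wilcoxon_paired")
  expect_lt(res$p, 0.01)
})

test_that("differential expression: null yields nothing, planted shifts are found, labels antisymmetric", {
  set.seed(35)
  n_arm <- 50
  g <- 200
  v <- matrix(rlnorm(g * 2 * n_arm, 2, 1), g, 2 * n_arm,
    dimnames = list(paste0("g", 1:g), paste0("s", 1:(2 * n_arm)))
  )
  tpm <- expr_matrix(sweep(v, 2, colSums(v), "/") * 1e6, "TPM")
  labels <- stats::setNames(rep(c("Q1", "Q4"), each = n_arm), sample_ids(tpm))
  null_res <- differential_expression(tpm, labels)
  expect_equal(sum(null_res$q < 0.001), 0L)
  expect_setequal(null_res$rank, seq_len(g))

  # swapping arms negates logFC exactly
  swapped <- stats::setNames(rep(c("Q4", "Q1"), each = n_arm), sample_ids(tpm))
  res_sw <- differential_expression(tpm, swapped)
  expect_equal(res_sw$logFC, -null_res$logFC, tolerance = 1e-12)

  # planted 4-fold shift in 50 of 550 genes, 100 per arm; planted genes are
  # low-abundance so the within-sample TPM renormalization barely dilutes the
  # planted fold change
  set.seed(36)
  n_arm <- 100
  g_bg <- 500
  g_pl <- 50
  base <- rbind(
    matrix(rlnorm(g_bg * 2 * n_arm, 2, 0.8), g_bg, 2 * n_arm),
    matrix(rlnorm(g_pl * 2 * n_arm, 0, 0.8), g_pl, 2 * n_arm)
  )
  dimnames(base) <- list(
    c(sprintf("bg%03d", 1:g_bg), sprintf("pl%02d", 1:g_pl)),
    paste0("s", 1:(2 * n_arm))
  )
  q4 <- (n_arm + 1):(2 * n_arm)
  base[g_bg + seq_len(g_pl), q4] <- base[g_bg + seq_len(g_pl), q4] * 4
  tpm2 <- expr_matrix(sweep(base, 2, colSums(base), "/") * 1e6, "TPM")
  lab2 <- stats::setNames(rep(c("Q1", "Q4"), each = n_arm), sample_ids(tpm2))
  res <- differential_expression(tpm2, lab2)
  planted <- grepl("^pl", res$gene_id)
  expect_gte(sum(res$significant[planted]), 45L)
  # the snake-plot order puts planted genes first
  expect_true(all(res$rank[planted] <= 60))
})
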