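test_that("loading deduplicates gene ids in file order and preserves shape", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene_id\ts1\ts2",
    "A\t1\t2",
    "A\t3\t4",
    "B\t5\t6"
  ), path)
  m <- load_expression(path, unit = "counts")
  expect_equal(gene_ids(m), c("A", "A.1", "B"))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(unname(m$values["A.1", ]), c(3, 4))

  # CSV dialect, zeros load fine under a TPM tag only if columns sum right,
  # so use counts here
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene_id,s1,s2", "A,0,0", "B,0,0", "C,0,0"), csv)
  z <- load_expression(csv, unit = "counts", dialect = "csv")
  expect_true(all(z$values == 0))
})

test_that("non-numeric cells raise a parse error naming the coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "A\t1\tNA", "B\t2\t3"), path)
  expect_error(load_expression(path, unit = "counts"), "'A'.*s2", ignore.case = TRUE)
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene_id\ts1", empty)
  expect_error(load_expression(empty, unit = "counts"), "empty")
})

test_that("filter_zero_genes keeps exactly the genes with signal", {
  v <- matrix(0, 2, 3, dimnames = list(c("a", "b"), paste0("s", 1:3)))
  v["b", ] <- c(1, 0, 2)
  m <- expr_matrix(v, "counts")
  f <- filter_zero_genes(m)
  expect_equal(gene_ids(f), "b")
  expect_equal(sample_ids(f), sample_ids(m))

  # no zero rows -> identity
  m2 <- random_expr(5, 4, seed = 1)
  expect_equal(filter_zero_genes(m2)$values, m2$values)

  # 100 random rows, 7 forced to zero -> 93 retained (count by direct scan)
  m3 <- random_expr(100, 6, seed = 2)
  m3$values[c(3, 11, 25, 40, 61, 88, 97), ] <- 0
  expect_equal(nrow(filter_zero_genes(m3)$values), 93L)
  expect_error(
    filter_zero_genes(expr_matrix(
      matrix(0, 2, 3, dimnames = list(c("a", "b"), paste0("s", 1:3))), "counts"
    )),
    "zero"
  )
})

test_that("counts_to_tpm normalizes length-corrected rates to 1e6 per sample", {
  v <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  m <- expr_matrix(v, "counts")
  tpm <- counts_to_tpm(m, c(a = 100, b = 200))
  # rates 0.1 and 0.05 -> 2/3 and 1/3 of a million
  expect_equal(unname(tpm$values[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-12)

  # single gene forced to 1e6; equal counts/lengths split evenly
  one <- expr_matrix(matrix(7, 1, 1, dimnames = list("g", "s")), "counts")
  expect_equal(unname(counts_to_tpm(one, c(g = 321))$values[1, 1]), 1e6)
  eq <- expr_matrix(matrix(c(4, 4), 2, 1, dimnames = list(c("a", "b"), "s")), "counts")
  expect_equal(unname(counts_to_tpm(eq, c(a = 50, b = 50))$values[, 1]), c(5e5, 5e5))

  expect_error(counts_to_tpm(m, c(a = 100)), "b")
  zero <- expr_matrix(matrix(c(0, 0), 2, 1, dimnames = list(c("a", "b"), "s")), "counts")
  expect_error(counts_to_tpm(zero, c(a = 1, b = 1)), "all-zero")
})

test_that("fpkm_to_tpm rescales proportionally, conserves 1e6, and is scale-invariant", {
  v <- matrix(c(5, 5, 1, 3), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  m <- expr_matrix(v, "FPKM")
  tpm <- fpkm_to_tpm(m)
  expect_equal(unname(tpm$values[, "s1"]), c(5e5, 5e5))
  expect_equal(unname(tpm$values[, "s2"]), c(2.5e5, 7.5e5))
  expect_equal(unname(colSums(tpm$values)), rep(1e6, 2), tolerance = 1e-9)

  # per-sample rescaling of FPKM leaves TPM unchanged; already-TPM input is a fixed point
  m2 <- expr_matrix(v * 37.5, "FPKM")
  expect_equal(fpkm_to_tpm(m2)$values, tpm$values, tolerance = 1e-12)
  again <- expr_matrix(tpm$values, "FPKM")
  expect_equal(fpkm_to_tpm(again)$values, tpm$values, tolerance = 1e-9)
})

test_that("log_transform is ln(TPM+1) and preserves within-sample ranks", {
  v <- matrix(c(0, exp(1) - 1, 10, 900), 2, 2,
    dimnames = list(c("a", "b"), c("s1", "s2"))
  )
  v <- sweep(v, 2, colSums(v), "/") * 1e6
  m <- expr_matrix(v, "TPM")
  lg <- log_transform(m)
  expect_equal(lg$unit, "logTPM")
  expect_equal(lg$values, log1p(v))
  r <- random_expr(20, 1, seed = 3)
  tpm <- expr_matrix(sweep(r$values, 2, colSums(r$values), "/") * 1e6, "TPM")
  expect_equal(
    rank(log_transform(tpm)$values[, 1]),
    rank(tpm$values[, 1])
  )
  expect_error(log_transform(m <- expr_matrix(v, "FPKM")), "TPM")
})

test_that("median_by_group matches the sort-based median per label", {
  m <- random_expr(10, 9, seed = 4)
  groups <- stats::setNames(rep(c("x", "y", "z"), each = 3), sample_ids(m))
  med <- median_by_group(m, groups)
  for (l in c("x", "y", "z")) {
    cols <- names(groups)[groups == l]
    manual <- apply(m$values[, cols], 1, function(v) sort(v)[2]) # n=3 -> middle
    expect_equal(unname(med[, l]), unname(manual))
  }
  # single-sample group returns that sample's values
  g1 <- stats::setNames(c("solo", rep("rest", 8)), sample_ids(m))
  expect_equal(unname(median_by_group(m, g1)[, "solo"]), unname(m$values[, 1]))
  expect_error(median_by_group(m, groups[-1]), "labeled")
})

test_that("gene sets round-trip through GMT and clinical tables through TSV", {
  sets <- list(APUC6 = c("HSD3B1", "HSD3B2", "CYP17A1"), SHR = c("ESR1", "PGR"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(sets, path)
  expect_equal(load_gene_sets(path), sets)

  clin <- data.frame(
    sample_id = c("p1", "p2"), os_months = c(10.5, 3), event = c(1, 0),
    biopsy_site = c("bone", "prostate"), histology = "adenocarcinoma",
    hormone_status = "sensitive", stringsAsFactors = FALSE
  )
  clin$claim_dates <- list(
    as.Date(c("2020-01-01", "2020-02-01")),
    as.Date("2020-01-15")
  )
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_clinical(clin, cpath)
  back <- load_clinical(cpath)
  expect_equal(back$os_months, clin$os_months)
  expect_equal(back$claim_dates, clin$claim_dates)
})
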