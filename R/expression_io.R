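#' Read an expression matrix from TSV or CSV
#'
#' Reads a delimited file with gene ids in the first column and sample ids in
#' the header row. Duplicate gene ids are made unique deterministically by
#' appending ".1", ".2", ... in file order, mirroring common public-cohort
#' preprocessing ("duplicate gene names were made unique"). Duplicates are
#' suffixed, never summed.
#'
#' @param path Path to the file.
#' @param unit Abundance unit tag of the stored values: `"counts"`, `"FPKM"`,
#'   `"TPM"` or `"logTPM"`.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return An [expr_matrix].
#' @export
load_expression <- function(path, unit = c("counts", "FPKM", "TPM", "logTPM"),
                            dialect = c("tsv", "csv")) {
  unit <- match.arg(unit)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(
    path,
    header = TRUE, sep = sep, check.names = FALSE,
    colClasses = "character", quote = "\"", comment.char = ""
  )
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty expression matrix in ", path)
  ids <- raw[[1L]]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(
    as.numeric(body),
    nrow = nrow(body),
    dimnames = list(NULL, colnames(body))
  ))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(
      "non-numeric cell '", body[bad[1L], bad[2L]], "' at gene '",
      ids[bad[1L]], "' (row ", bad[1L], "), sample '",
      colnames(body)[bad[2L]], "' (column ", bad[2L], ")"
    )
  }
  rownames(num) <- dedup_gene_ids(ids)
  expr_matrix(num, unit)
}

# "A, A, B" -> "A, A.1, B": first occurrence keeps its name, later ones get
# .1, .2, ... in file order.
dedup_gene_ids <- function(ids) {
  counts <- new.env(parent = emptyenv())
  vapply(ids, function(id) {
    k <- if (is.null(counts[[id]])) 0L else counts[[id]]
    counts[[id]] <- k + 1L
    if (k == 0L) id else paste0(id, ".", k)
  }, character(1), USE.NAMES = FALSE)
}

#' Write an expression matrix to TSV
#'
#' @param m An [expr_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(gene_id = gene_ids(m), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop genes with zero expression across all samples
#'
#' @param m An [expr_matrix].
#' @return An [expr_matrix] containing exactly the genes with at least one
#'   non-zero value; the sample set is unchanged.
#' @export
filter_zero_genes <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  keep <- rowSums(m$values != 0) > 0
  if (!any(keep)) stop("all genes have zero expression across all samples")
  expr_matrix(m$values[keep, , drop = FALSE], m$unit)
}

#' Convert raw counts to TPM using effective transcript lengths
#'
#' Per sample, `rate_g = count_g / length_g` and
#' `TPM_g = 1e6 * rate_g / sum(rate)`, so every column sums to 1e6. This is
#' the within-sample normalization used when public raw-count cohorts are
#' harmonized to TPM.
#'
#' @param m An [expr_matrix] with `unit = "counts"`.
#' @param lengths Named numeric vector of effective transcript lengths in base
#'   pairs (> 0), covering every gene in `m`.
#' @return An [expr_matrix] with `unit = "TPM"`.
#' @export
counts_to_tpm <- function(m, lengths) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "counts") stop("counts_to_tpm expects unit 'counts', got '", m$unit, "'")
  if (is.null(names(lengths))) stop("`lengths` must be a named vector (gene_id -> length)")
  missing <- setdiff(gene_ids(m), names(lengths))
  if (length(missing)) {
    stop("missing transcript lengths for: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  len <- lengths[gene_ids(m)]
  if (any(!is.finite(len)) || any(len <= 0)) stop("transcript lengths must be positive")
  rate <- m$values / len
  tot <- colSums(rate)
  if (any(tot == 0)) {
    stop(
      "sample(s) with all-zero counts: ",
      paste(utils::head(sample_ids(m)[tot == 0], 5), collapse = ", ")
    )
  }
  expr_matrix(sweep(rate, 2, tot, "/") * 1e6, "TPM")
}

#' Convert FPKM to TPM
#'
#' `TPM_g = 1e6 * FPKM_g / sum(FPKM)` per sample; the transform is invariant
#' to any per-sample rescaling of FPKM.
#'
#' @param m An [expr_matrix] with `unit = "FPKM"`.
#' @return An [expr_matrix] with `unit = "TPM"`.
#' @export
fpkm_to_tpm <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "FPKM") stop("fpkm_to_tpm expects unit 'FPKM', got '", m$unit, "'")
  tot <- colSums(m$values)
  if (any(tot == 0)) {
    stop(
      "sample(s) with all-zero FPKM: ",
      paste(utils::head(sample_ids(m)[tot == 0], 5), collapse = ", ")
    )
  }
  expr_matrix(sweep(m$values, 2, tot, "/") * 1e6, "TPM")
}

#' Natural-log transform of TPM
#'
#' Element-wise `ln(TPM + 1)`. Monotone, so within-sample ranks are preserved.
#'
#' @param m An [expr_matrix] with `unit = "TPM"`.
#' @return An [expr_matrix] with `unit = "logTPM"`.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "TPM") stop("log_transform expects unit 'TPM', got '", m$unit, "'")
  if (any(m$values < 0)) stop("negative TPM values")
  expr_matrix(log1p(m$values), "logTPM")
}

#' Per-group median expression
#'
#' Cell (g, l) is the median of gene g over the samples labeled l; used e.g.
#' to summarize gene expression across tissue sites.
#'
#' @param m An [expr_matrix].
#' @param groups Named character vector or factor mapping every sample id of
#'   `m` to a group label.
#' @return A gene x label numeric matrix of medians.
#' @export
median_by_group <- function(m, groups) {
  stopifnot(inherits(m, "expr_matrix"))
  groups <- groups[sample_ids(m)]
  if (anyNA(groups)) stop("every sample must be labeled")
  labs <- unique(as.character(groups))
  out <- vapply(labs, function(l) {
    cols <- which(as.character(groups) == l)
    if (!length(cols)) stop("empty group: ", l)
    apply(m$values[, cols, drop = FALSE], 1, stats::median)
  }, numeric(nrow(m$values)))
  if (nrow(m$values) == 1L) out <- matrix(out, nrow = 1, dimnames = list(gene_ids(m), labs))
  out
}

#' Read gene sets from a GMT file or a plain gene list
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`. Plain files
#' hold one gene per line and yield a single set named after the file.
#'
#' @param path Path to the file.
#' @param format `"gmt"` or `"list"`.
#' @return Named list of character vectors.
#' @export
load_gene_sets <- function(path, format = c("gmt", "list")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no gene sets in ", path)
  if (format == "list") {
    set <- list(trimws(lines))
    names(set) <- tools::file_path_sans_ext(basename(path))
    return(set)
  }
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop("malformed GMT line: ", paste(f, collapse = "\t"))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  sets
}

#' Write gene sets to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, genes) {
    paste(c(nm, d, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table
#'
#' Expects TSV columns `sample_id`, `os_months`, `event`, and optionally
#' `biopsy_site`, `histology`, `hormone_status`, `claim_dates` (ISO dates,
#' semicolon-separated, strictly increasing per patient).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame`; `claim_dates`, when present, is a list-column of
#'   `Date` vectors.
#' @export
load_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(
    path,
    header = TRUE, sep = "\t", check.names = FALSE,
    stringsAsFactors = FALSE, quote = "\"", comment.char = ""
  )
  required <- c("sample_id", "os_months", "event")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) stop("clinical table lacks column(s): ", paste(missing, collapse = ", "))
  validate_clinical(df)
  if ("claim_dates" %in% colnames(df)) {
    df$claim_dates <- lapply(strsplit(as.character(df$claim_dates), ";", fixed = TRUE), function(d) {
      d <- as.Date(trimws(d))
      if (anyNA(d)) stop("unparseable claim date")
      if (is.unsorted(d, strictly = TRUE)) stop("claim dates must be strictly increasing")
      d
    })
  }
  df
}

validate_clinical <- function(df) {
  if (any(df$os_months < 0)) stop("os_months must be >= 0")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in clinical table")
  invisible(df)
}

#' Write a clinical table to TSV
#'
#' @param df Clinical `data.frame` as returned by [load_clinical] or
#'   [generate_clinical]; a `claim_dates` list-column is serialized as
#'   semicolon-separated ISO dates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(df, path) {
  out <- df
  if ("claim_dates" %in% colnames(out) && is.list(out$claim_dates)) {
    out$claim_dates <- vapply(
      out$claim_dates,
      function(d) paste(format(d, "%Y-%m-%d"), collapse = ";"),
      character(1)
    )
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
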