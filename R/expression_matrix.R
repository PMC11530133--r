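#' Expression matrix with a declared abundance unit
#'
#' A light container for a gene x sample expression matrix. Genes are rows,
#' samples are columns, and the abundance unit travels with the data so that
#' downstream operations can refuse inputs on the wrong scale.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene ids, column names are sample ids; both must be unique.
#' @param unit One of `"counts"`, `"FPKM"`, `"TPM"`, `"logTPM"`.
#'
#' @details Values must be non-negative unless `unit = "logTPM"` (the log
#'   transform keeps them non-negative anyway, but the invariant is only
#'   enforced on linear-scale units). When `unit = "TPM"` every sample column
#'   must sum to 1e6 within relative tolerance 1e-6.
#'
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, unit = c("counts", "FPKM", "TPM", "logTPM")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("expression matrix is empty")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  if (anyNA(values)) stop("expression values contain NA")
  if (unit != "logTPM" && any(values < 0)) {
    stop("negative values are not allowed for unit '", unit, "'")
  }
  if (unit == "TPM") {
    cs <- colSums(values)
    bad <- abs(cs - 1e6) > 1e6 * 1e-6
    if (any(bad)) {
      stop(
        "TPM columns must sum to 1e6; offending samples: ",
        paste(utils::head(colnames(values)[bad], 5), collapse = ", ")
      )
    }
  }
  structure(list(values = values, unit = unit), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(
    "<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
    " samples [", x$unit, "]\n",
    sep = ""
  )
  invisible(x)
}

#' Gene and sample identifiers of an expression matrix
#'
#' @param x An `expr_matrix`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  rownames(x$values)
}

#' @rdname gene_ids
#' @export
sample_ids <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  colnames(x$values)
}
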