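#' Expression matrix container
#'
#' A light-weight genes x samples container in the style of edgeR's
#' `DGEList`: a numeric matrix with unique row (gene) and column (sample)
#' names plus a flag recording whether the values are raw counts (RNA-seq)
#' or pre-normalized intensities (e.g. RMA microarray). Count-specific
#' steps ([filter_genes_cpm()], [tmm_factors()]) refuse normalized input.
#'
#' @param values numeric genes x samples matrix, non-negative, with unique
#'   `rownames` (gene IDs) and `colnames` (sample IDs).
#' @param data_kind `"counts"` or `"normalized"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `data_kind`.
#' @examples
#' m <- expression_matrix(matrix(rpois(12, 10), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4))))
#' dim(m)
#' @export
expression_matrix <- function(values, data_kind = c("counts", "normalized")) {
  data_kind <- match.arg(data_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene IDs; resolve with dedupe_genes() using an ID map")
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample IDs")
  if (any(values < 0)) stop("negative expression values")
  structure(list(values = values, data_kind = data_kind),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$data_kind))
  invisible(x)
}

#' Gene and sample identifiers
#' @param m an `ExpressionMatrix`.
#' @return Character vector of IDs.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' Per-sample metadata table
#'
#' Validates a per-sample metadata `data.frame` for use with an expression
#' matrix. Required columns: `sample_id`, `patient_id`, `visit_rank`
#' (0-based integer order of the visit within its patient; gaps are allowed
#' and encode missing visits). Optional: `visit_label` and any number of
#' covariate columns (e.g. PASI, acuity, group).
#'
#' @param df a data.frame with at least `sample_id`, `patient_id`,
#'   `visit_rank`.
#' @return The validated data.frame with class `c("SampleMeta","data.frame")`,
#'   ordered by (patient_id, visit_rank).
#' @export
sample_meta <- function(df) {
  req <- c("sample_id", "patient_id", "visit_rank")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$patient_id <- as.character(df$patient_id)
  df$visit_rank <- as.integer(df$visit_rank)
  if (anyNA(df$visit_rank) || any(df$visit_rank < 0))
    stop("visit_rank must be a non-negative integer")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")
  if (anyDuplicated(df[c("patient_id", "visit_rank")]))
    stop("duplicated (patient_id, visit_rank) pair in metadata")
  if (!"visit_label" %in% names(df))
    df$visit_label <- paste0("V", df$visit_rank)
  df <- df[order(df$patient_id, df$visit_rank), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("SampleMeta", "data.frame")
  df
}
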