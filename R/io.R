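#' Read an expression matrix from delimited text
#'
#' Expects genes in rows, a header line of sample IDs, and gene IDs in the
#' first column. Separator is inferred from the extension (`.csv` = comma,
#' otherwise tab) unless given.
#'
#' @param path file path.
#' @param data_kind passed to [expression_matrix()].
#' @param sep field separator; `NULL` = infer from extension.
#' @return An `ExpressionMatrix`.
#' @export
read_expression_delim <- function(path, data_kind = "counts", sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  expression_matrix(as.matrix(df), data_kind)
}

#' @rdname read_expression_delim
#' @param m an `ExpressionMatrix` to write.
#' @export
write_expression_delim <- function(m, path, sep = "\t") {
  df <- data.frame(gene_id = gene_ids(m), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write an expression matrix in MatrixMarket triplet format
#'
#' The sparse values go to `<path>`, gene IDs to `<path>.rownames` and
#' sample IDs to `<path>.colnames` (one per line), the usual sidecar-file
#' convention for `.mtx` exports.
#'
#' @param path path of the `.mtx` file.
#' @param data_kind passed to [expression_matrix()].
#' @return An `ExpressionMatrix`.
#' @export
read_expression_mm <- function(path, data_kind = "counts") {
  v <- as.matrix(Matrix::readMM(path))
  rn <- readLines(paste0(path, ".rownames"))
  cn <- readLines(paste0(path, ".colnames"))
  dimnames(v) <- list(rn, cn)
  expression_matrix(v, data_kind)
}

#' @rdname read_expression_mm
#' @param m an `ExpressionMatrix` to write.
#' @export
write_expression_mm <- function(m, path) {
  Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), path)
  writeLines(gene_ids(m), paste0(path, ".rownames"))
  writeLines(sample_ids(m), paste0(path, ".colnames"))
  invisible(path)
}

#' Read an AnnData-style HDF5 container
#'
#' Reads `X` (dense, CSR or CSC), `obs/_index` (samples) and `var/_index`
#' (genes) from an `.h5ad` file and transposes to genes x samples. Requires
#' the optional rhdf5 package.
#'
#' @param path `.h5ad` file path.
#' @param data_kind passed to [expression_matrix()].
#' @return An `ExpressionMatrix`.
#' @export
read_expression_h5ad <- function(path, data_kind = "counts") {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading HDF5 containers requires the 'rhdf5' package")
  read_idx <- function(grp) {
    attrs <- rhdf5::h5readAttributes(path, grp)
    key <- if (!is.null(attrs[["_index"]])) attrs[["_index"]] else "_index"
    as.character(rhdf5::h5read(path, paste0(grp, "/", key)))
  }
  obs <- read_idx("obs")  # samples (AnnData rows)
  var <- read_idx("var")  # genes  (AnnData cols)
  xattr <- tryCatch(rhdf5::h5readAttributes(path, "X"), error = function(e) list())
  enc <- xattr[["encoding-type"]]
  if (!is.null(enc) && enc %in% c("csr_matrix", "csc_matrix")) {
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    shape <- as.integer(xattr[["shape"]])  # (n_obs, n_var)
    sm <- if (enc == "csr_matrix") {
      Matrix::sparseMatrix(j = indices + 1L, p = indptr, x = data,
                           dims = shape, repr = "C", index1 = TRUE)
    } else {
      Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                           dims = shape, repr = "C", index1 = TRUE)
    }
    x <- as.matrix(sm)
  } else {
    x <- rhdf5::h5read(path, "X")
    # HDF5 stores row-major (n_obs, n_var); rhdf5 returns it transposed
    if (nrow(x) == length(var) && ncol(x) == length(obs)) {
      dimnames(x) <- list(var, obs)
      return(expression_matrix(x, data_kind))
    }
  }
  dimnames(x) <- list(obs, var)
  expression_matrix(t(x), data_kind)
}

#' Read sample metadata from delimited text
#'
#' @param path file with a header containing at least `sample_id`,
#'   `patient_id`, `visit_rank`.
#' @param sep separator; `NULL` = infer from extension.
#' @return A `SampleMeta` data.frame.
#' @export
read_sample_meta <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  sample_meta(utils::read.table(path, header = TRUE, sep = sep,
                                check.names = FALSE, stringsAsFactors = FALSE))
}

#' Load and join an expression matrix with its sample metadata
#'
#' Samples present in only one of the two inputs are dropped with a warning
#' reporting the count; zero overlap is an error.
#'
#' @param expr_path path to the expression matrix.
#' @param meta_path path to the metadata table.
#' @param format `"delimited"`, `"mm"` (MatrixMarket + sidecars) or `"h5ad"`.
#' @param data_kind passed to the matrix reader.
#' @return list with `matrix` (`ExpressionMatrix`) and `meta` (`SampleMeta`),
#'   aligned on sample_id.
#' @export
load_dataset <- function(expr_path, meta_path,
                         format = c("delimited", "mm", "h5ad"),
                         data_kind = "counts") {
  format <- match.arg(format)
  m <- switch(format,
              delimited = read_expression_delim(expr_path, data_kind),
              mm = read_expression_mm(expr_path, data_kind),
              h5ad = read_expression_h5ad(expr_path, data_kind))
  meta <- read_sample_meta(meta_path)
  common <- intersect(sample_ids(m), meta$sample_id)
  if (!length(common)) stop("no overlapping samples between matrix and metadata")
  n_drop <- (ncol(m$values) - length(common)) + (nrow(meta) - length(common))
  if (n_drop > 0)
    warning(sprintf("dropping %d sample(s) present in only one input", n_drop))
  m <- expression_matrix(m$values[, common, drop = FALSE], m$data_kind)
  meta <- sample_meta(as.data.frame(meta[meta$sample_id %in% common, ,
                                         drop = FALSE]))
  list(matrix = m, meta = meta)
}

#' Write TMM factors as a two-column TSV
#' @param factors named vector from [tmm_factors()].
#' @param path output path.
#' @export
write_tmm_factors <- function(factors, path) {
  utils::write.table(data.frame(sample_id = names(factors), factor = factors),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
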