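#' Filter lowly expressed genes by CPM
#'
#' Keeps genes whose counts-per-million exceed `cpm_threshold` (strictly)
#' in at least `ceiling(min_fraction * n_samples)` samples. CPM is computed
#' against the library sizes of the *input* matrix (pre-filter column sums),
#' so the operation is idempotent. Defaults reproduce the common
#' ">0.25 CPM in at least 1% of samples" rule for clinical bulk RNA-seq.
#'
#' @param m an `ExpressionMatrix` with `data_kind = "counts"`.
#' @param cpm_threshold strict CPM cutoff (default 0.25).
#' @param min_fraction minimum fraction of samples that must pass (default 0.01).
#' @return The filtered `ExpressionMatrix`; samples unchanged.
#' @export
filter_genes_cpm <- function(m, cpm_threshold = 0.25, min_fraction = 0.01) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$data_kind != "counts")
    stop("CPM filtering requires raw counts; got normalized values")
  stopifnot(cpm_threshold > 0, min_fraction > 0, min_fraction <= 1)
  lib <- colSums(m$values)
  if (any(lib == 0))
    stop("CPM undefined: all-zero sample column(s): ",
         paste(colnames(m$values)[lib == 0], collapse = ", "))
  cpm <- sweep(m$values, 2, lib, "/") * 1e6
  need <- ceiling(min_fraction * ncol(m$values))
  keep <- rowSums(cpm > cpm_threshold) >= need
  expression_matrix(m$values[keep, , drop = FALSE], m$data_kind)
}

#' Collapse duplicate gene identifiers
#'
#' Maps gene IDs (e.g. Ensembl IDs or probesets) to symbols and, whenever
#' several rows map to the same symbol, keeps only the row with the highest
#' arithmetic row mean of the values as given (ties broken by first
#' occurrence in row order). Output rows are labeled by symbol.
#'
#' @param m an `ExpressionMatrix`.
#' @param id_map named character vector, `names(id_map)` = current gene IDs,
#'   values = target symbols; must cover every gene in `m`.
#' @return An `ExpressionMatrix` with unique symbol row names.
#' @export
dedupe_genes <- function(m, id_map) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  ids <- gene_ids(m)
  miss <- setdiff(ids, names(id_map))
  if (length(miss))
    stop("id_map does not cover ", length(miss), " gene ID(s), e.g. ", miss[1])
  sym <- unname(id_map[ids])
  mu <- rowMeans(m$values)
  # per symbol, index of the max-mean row; which.max takes the first on ties
  keep <- vapply(split(seq_along(sym), sym), function(idx) idx[which.max(mu[idx])],
                 integer(1))
  keep <- sort(keep)  # preserve original row order
  v <- m$values[keep, , drop = FALSE]
  rownames(v) <- sym[keep]
  expression_matrix(v, m$data_kind)
}

#' TMM scaling factors
#'
#' Trimmed-mean-of-M-values scaling factors (Robinson & Oshlack), computed
#' with the canonical edgeR implementation: 30% trim on M-values, 5% trim on
#' A-values, precision weighting, and factors normalized so their log mean
#' is zero. Downstream normalized values are CPM divided by the factor (see
#' [normalize_expression()]).
#'
#' @param m an `ExpressionMatrix` with `data_kind = "counts"`.
#' @param ref_sample optional sample ID to use as the reference column;
#'   default picks the sample whose 75th percentile (of CPM) is closest to
#'   the mean 75th percentile.
#' @return Named numeric vector of positive factors, one per sample.
#' @export
tmm_factors <- function(m, ref_sample = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$data_kind != "counts") stop("TMM requires raw counts")
  if (ncol(m$values) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(m$values)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(m$values)[lib == 0], collapse = ", "))
  ref_col <- NULL
  if (!is.null(ref_sample)) {
    ref_col <- match(ref_sample, sample_ids(m))
    if (is.na(ref_col)) stop("ref_sample not found: ", ref_sample)
  }
  f <- edgeR::calcNormFactors(m$values, method = "TMM", refColumn = ref_col)
  names(f) <- sample_ids(m)
  f
}

#' CPM normalization with TMM factors
#'
#' Converts counts to TMM-scaled counts-per-million:
#' `values[g,s] / (lib_size[s] * factor[s]) * 1e6`.
#'
#' @param m an `ExpressionMatrix` with `data_kind = "counts"`.
#' @param factors named factor vector from [tmm_factors()]; default recomputes.
#' @return An `ExpressionMatrix` with `data_kind = "normalized"`.
#' @export
normalize_expression <- function(m, factors = tmm_factors(m)) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$data_kind != "counts") stop("normalize_expression expects counts")
  factors <- factors[sample_ids(m)]
  if (anyNA(factors)) stop("factors missing for some samples")
  lib <- colSums(m$values)
  v <- sweep(m$values, 2, lib * factors, "/") * 1e6
  expression_matrix(v, "normalized")
}

#' Standard count preprocessing pipeline
#'
#' filter -> (optional dedup) -> TMM -> CPM, the usual route from raw bulk
#' RNA-seq counts to values ready for embedding. Externally batch-corrected
#' or GC-normalized matrices can be passed straight to [pca_embed()]
#' instead. Matrices with `data_kind = "normalized"` (e.g. RMA microarray)
#' skip filtering and TMM; only deduplication applies.
#'
#' @param m an `ExpressionMatrix`.
#' @param id_map optional gene->symbol map for [dedupe_genes()].
#' @inheritParams filter_genes_cpm
#' @return list with `matrix` (normalized `ExpressionMatrix`) and `factors`
#'   (TMM factors, `NULL` for normalized input).
#' @export
preprocess_counts <- function(m, id_map = NULL, cpm_threshold = 0.25,
                              min_fraction = 0.01) {
  if (m$data_kind == "normalized") {
    if (!is.null(id_map)) m <- dedupe_genes(m, id_map)
    return(list(matrix = m, factors = NULL))
  }
  m <- filter_genes_cpm(m, cpm_threshold, min_fraction)
  if (!is.null(id_map)) m <- dedupe_genes(m, id_map)
  f <- tmm_factors(m)
  list(matrix = normalize_expression(m, f), factors = f)
}
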