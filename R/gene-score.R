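#' Kolmogorov-Smirnov gene scores between two sample groups
#'
#' Per gene, a two-sided two-sample KS test compares the expression
#' distributions of the two groups (typically diseased vs healthy);
#' p-values are Benjamini-Hochberg adjusted across genes and the score is
#'
#'   `score = -log10(adj. p) * log2(FC)`,
#'
#' with `FC = (mean_a + pseudocount) / (mean_b + pseudocount)` on the
#' normalized linear scale. Genes constant across both groups get p = 1 and
#' score 0. Adjusted p-values are floored at 1e-300 before the log.
#'
#' @param m an `ExpressionMatrix` (normalized values recommended).
#' @param group_a,group_b disjoint sample ID sets, each with >= 3 samples.
#' @param fc_pseudocount pseudocount added to both group means (default 1).
#' @return data.frame sorted by score descending: `gene_id`, `statistic`,
#'   `p_value`, `adj_p`, `log2_fc`, `score`.
#' @export
score_genes <- function(m, group_a, group_b, fc_pseudocount = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs at least 3 samples")
  miss <- setdiff(c(group_a, group_b), sample_ids(m))
  if (length(miss)) stop("samples not in matrix: ", paste(miss, collapse = ", "))
  va <- m$values[, group_a, drop = FALSE]
  vb <- m$values[, group_b, drop = FALSE]
  n_genes <- nrow(m$values)
  stat <- p <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    a <- va[g, ]; b <- vb[g, ]
    if (max(a, b) == min(a, b)) {       # constant in both groups
      stat[g] <- 0; p[g] <- 1
    } else {
      kt <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
      stat[g] <- unname(kt$statistic); p[g] <- kt$p.value
    }
  }
  adj <- stats::p.adjust(p, method = "BH")
  mu_a <- rowMeans(va); mu_b <- rowMeans(vb)
  lfc <- log2((mu_a + fc_pseudocount) / (mu_b + fc_pseudocount))
  score <- -log10(pmax(adj, 1e-300)) * lfc
  out <- data.frame(gene_id = gene_ids(m), statistic = stat, p_value = p,
                    adj_p = adj, log2_fc = lfc, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a prerank file for enrichment tools
#'
#' Writes the header-less two-column tab-separated (gene, score) file that
#' prerank-style GSEA consumers expect, sorted by score descending.
#'
#' @param scores data.frame from [score_genes()] (needs `gene_id`, `score`).
#' @param path output path (conventionally `.rnk`).
#' @export
export_prerank <- function(scores, path) {
  stopifnot(nrow(scores) > 0)
  if (anyDuplicated(scores$gene_id)) stop("duplicate gene_id in scores")
  ord <- order(-scores$score, scores$gene_id)
  utils::write.table(scores[ord, c("gene_id", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname export_prerank
#' @export
write_gene_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
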