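#' Differential expression between two sample groups
#'
#' Wilcoxon rank-sum test per feature with Benjamini-Hochberg correction
#' across all features tested at the given level. A feature is significant
#' when |log2 fold change| > `lfc_threshold` and FDR < `fdr_threshold`
#' (defaults 1 and 0.05). Fold change is computed on group means with a
#' pseudocount: `log2((mean_a + eps) / (mean_b + eps))`, eps = 0.01. The
#' rank-sum p-value is exact for small samples without ties and a normal
#' approximation with tie/continuity correction otherwise (via
#' [stats::wilcox.test()]).
#'
#' At `level = "gene"` expression is the sum of member-transcript TPMs.
#' When structural `calls` are supplied, incomplete-splice-match (ISM)
#' transcripts — likely degradation artifacts — are excluded before testing.
#'
#' @param em An `expression_matrix`.
#' @param group_a,group_b Group labels (each with >= 2 samples); fold change
#'   is a-over-b.
#' @param level `"transcript"` or `"gene"`.
#' @param tx2gene Named character vector transcript_id -> gene_id (required
#'   for gene level).
#' @param calls Optional structural-call data.frame used to drop ISM
#'   transcripts.
#' @param lfc_threshold,fdr_threshold Significance thresholds.
#' @param eps Pseudocount for fold changes.
#' @param paired Use the paired signed-rank test (samples matched by order
#'   within each group). Default unpaired.
#' @return data.frame: feature_id, mean_a, mean_b, log2_fc, p_value, fdr,
#'   is_significant.
#' @export
differential_expression <- function(em, group_a, group_b,
                                    level = c("transcript", "gene"),
                                    tx2gene = NULL, calls = NULL,
                                    lfc_threshold = 1, fdr_threshold = 0.05,
                                    eps = 0.01, paired = FALSE) {
  stopifnot(inherits(em, "expression_matrix"))
  level <- match.arg(level)
  if (nrow(em$values) == 0L) stop("empty expression matrix")
  sa <- group_samples(em, group_a); sb <- group_samples(em, group_b)
  if (length(sa) < 2L || length(sb) < 2L)
    stop("both groups need >= 2 samples")
  vals <- em$values
  if (!is.null(calls)) {
    ism <- calls$transcript_id[calls$category == "ISM"]
    vals <- vals[!rownames(vals) %in% ism, , drop = FALSE]
  }
  if (level == "gene") {
    if (is.null(tx2gene)) stop("tx2gene is required at gene level")
    missing <- setdiff(rownames(vals), names(tx2gene))
    if (length(missing))
      stop("transcripts missing from tx2gene: ",
           paste(utils::head(missing, 3L), collapse = ", "))
    vals <- rowsum(vals, group = tx2gene[rownames(vals)])
  }
  a <- vals[, sa, drop = FALSE]; b <- vals[, sb, drop = FALSE]
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  p <- vapply(seq_len(nrow(vals)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (all(x == x[1L]) && all(y == y[1L]) && x[1L] == y[1L]) return(1)
    suppressWarnings(stats::wilcox.test(x, y, paired = paired)$p.value)
  }, 0)
  fdr <- stats::p.adjust(p, method = "BH")
  log2_fc <- log2((mean_a + eps) / (mean_b + eps))
  data.frame(feature_id = rownames(vals), mean_a = mean_a, mean_b = mean_b,
             log2_fc = log2_fc, p_value = p, fdr = fdr,
             is_significant = abs(log2_fc) > lfc_threshold & fdr < fdr_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Decompose differential signal into transcript-only, gene-only and shared
#'
#' A gene is "DET-positive" when at least one member transcript is
#' significant at the transcript level. The decomposition partitions genes
#' with any significant signal into: DET-specific (transcript-level signal
#' without gene-level significance — isoform-level changes invisible to
#' gene-level analysis), DEG-specific, and shared.
#'
#' @param det Transcript-level results from [differential_expression()].
#' @param deg Gene-level results from the same cohort.
#' @param tx2gene Named character vector transcript_id -> gene_id covering
#'   every tested transcript.
#' @return List of class `overlap_decomposition`: det_specific_genes,
#'   deg_specific_genes, shared_genes (sorted id vectors) and `counts`.
#' @export
overlap_decomposition <- function(det, deg, tx2gene) {
  missing <- setdiff(det$feature_id, names(tx2gene))
  if (length(missing))
    stop("transcripts missing from tx2gene: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  det_genes <- sort(unique(tx2gene[det$feature_id[det$is_significant]]))
  deg_genes <- sort(unique(deg$feature_id[deg$is_significant]))
  out <- list(det_specific_genes = setdiff(det_genes, deg_genes),
              deg_specific_genes = setdiff(deg_genes, det_genes),
              shared_genes = intersect(det_genes, deg_genes))
  out$counts <- vapply(out, length, 0L)
  class(out) <- "overlap_decomposition"
  out
}

#' @export
print.overlap_decomposition <- function(x, ...) {
  cat(sprintf("<overlap_decomposition> DET-specific %d | shared %d | DEG-specific %d\n",
              x$counts[["det_specific_genes"]], x$counts[["shared_genes"]],
              x$counts[["deg_specific_genes"]]))
  invisible(x)
}
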